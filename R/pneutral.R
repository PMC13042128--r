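# Per-gene Bayesian mixture over pLoF allele counts: each observed variant's
# frequency is drawn either from a neutral spectrum learned from exome-wide
# synonymous variants (misannotation component) or from the gamma spectrum
# under selection. A grid posterior over (s_het, w) yields the posterior
# mean selection coefficient and, for every variant, the posterior mean
# probability of neutrality p_neutral.

#' Fit the neutral allele-count spectrum from synonymous variants
#'
#' Class-conditional empirical distribution of allele counts among observed
#' (AC >= 1) synonymous variants, smoothed with a pseudocount. Counts above
#' `tail_start` are pooled into log-uniform bins up to `n_chrom`, and the
#' fitted probability of an AC inside a tail bin is the bin mass divided by
#' the number of allele counts the bin spans. Classes with fewer than
#' `min_per_class` variants fall back to the pooled spectrum with a warning.
#'
#' @param variants Variant data frame; rows with `consequence ==
#'   "synonymous"` and `ac >= 1` are used. Needs a `class` column or the
#'   context columns for [classify_mutation()].
#' @param n_chrom Chromosome sample size the spectrum is conditioned on.
#' @param pseudocount Added to every bin. Default 0.5.
#' @param tail_start First allele count of the binned tail. Default 100.
#' @param n_tail_bins Number of log-uniform tail bins. Default 30.
#' @param min_per_class Minimum synonymous variants for a class-specific
#'   fit. Default 100.
#' @return Object of class `neutral_sfs_model`.
#' @export
fit_neutral_sfs <- function(variants, n_chrom, pseudocount = 0.5,
                            tail_start = 100L, n_tail_bins = 30L,
                            min_per_class = 100L) {
  syn <- variants[variants$consequence == "synonymous" & variants$ac >= 1, ,
                  drop = FALSE]
  if (!nrow(syn)) stop("no observed synonymous variants to fit from")
  cls <- if ("class" %in% names(syn)) {
    syn$class
  } else {
    classify_mutation(syn$context, syn$alt, syn$methylation)
  }
  breaks <- sfs_breaks(n_chrom, tail_start, n_tail_bins)

  fit_one <- function(ac) {
    bin <- findInterval(ac, breaks$lower)
    mass <- tabulate(bin, nbins = length(breaks$lower)) + pseudocount
    mass / sum(mass)
  }
  pooled <- fit_one(syn$ac)
  by_class <- list()
  for (cl in MUTATION_CLASSES) {
    ac_cl <- syn$ac[cls == cl]
    if (length(ac_cl) >= min_per_class) {
      by_class[[cl]] <- fit_one(ac_cl)
    } else {
      warning(sprintf(
        "class %s has %d synonymous variants (< %d); using pooled spectrum",
        cl, length(ac_cl), min_per_class
      ), call. = FALSE)
      by_class[[cl]] <- pooled
    }
  }
  structure(
    list(
      by_class = by_class, pooled = pooled, breaks = breaks,
      n_chrom = n_chrom, pseudocount = pseudocount
    ),
    class = "neutral_sfs_model"
  )
}

# Bin layout: AC 1 .. tail_start-1 singly, then n_tail_bins log-uniform bins
# covering tail_start .. n_chrom. Returns lower bounds and bin widths (in
# allele-count units).
sfs_breaks <- function(n_chrom, tail_start = 100L, n_tail_bins = 30L) {
  tail_start <- min(tail_start, n_chrom)
  lower <- seq_len(tail_start - 1L)
  if (n_chrom >= tail_start) {
    tl <- unique(round(exp(seq(log(tail_start), log(n_chrom + 1),
                               length.out = n_tail_bins + 1L))))
    lower <- c(lower, tl[-length(tl)])
    upper <- c(seq_len(tail_start - 1L) + 1L, tl[-1L])
  } else {
    upper <- lower + 1L
  }
  list(lower = lower, width = upper - lower)
}

#' Neutral probability of an observed allele count
#'
#' @param model A [fit_neutral_sfs()] model.
#' @param ac Allele counts (>= 1).
#' @param class Mutational class labels (recycled).
#' @return Probability of each AC under the class's neutral spectrum.
#' @export
neutral_pmf <- function(model, ac, class) {
  stopifnot(inherits(model, "neutral_sfs_model"), all(ac >= 1))
  n <- max(length(ac), length(class))
  ac <- rep_len(ac, n)
  class <- rep_len(class, n)
  bin <- findInterval(ac, model$breaks$lower)
  out <- numeric(n)
  for (cl in unique(class)) {
    idx <- class == cl
    pr <- if (cl %in% names(model$by_class)) {
      model$by_class[[cl]]
    } else {
      model$pooled
    }
    out[idx] <- pr[bin[idx]] / model$breaks$width[bin[idx]]
  }
  out
}

#' Allele-count distribution under selection, conditioned on observation
#'
#' The gamma frequency spectrum sampled with Poisson noise gives a negative
#' binomial allele count with size `4 N_e mu` and mean `n_chrom mu / s_het`;
#' this returns its pmf renormalised over `1 <= AC <= n_chrom` (the model
#' only ever sees observed variants). Mass shifts towards singletons as
#' `s_het` grows.
#'
#' @param ac Allele count(s) >= 1.
#' @param mu Per-site mutation rate(s).
#' @param s_het Heterozygous selection coefficient.
#' @param n_chrom Chromosome sample size.
#' @param N_e Effective population size. Default 1e4.
#' @return Probability vector.
#' @export
selection_pmf <- function(ac, mu, s_het, n_chrom, N_e = 1e4) {
  if (any(ac < 1)) stop("selection_pmf is conditioned on AC >= 1")
  if (any(mu <= 0) || any(s_het <= 0) || n_chrom <= 0) {
    stop("invalid parameters")
  }
  p <- nb_params(mu, s_het, n_chrom, N_e)
  norm <- pnbinom(n_chrom, size = p$size, prob = 1 - p$pi) -
    dnbinom(0, size = p$size, prob = 1 - p$pi)
  dnbinom(ac, size = p$size, prob = 1 - p$pi) / norm
}

#' Joint posterior over selection strength and misannotation weight
#'
#' For one gene's observed pLoF variants, computes the grid posterior over
#' `(s_het, w)` with likelihood
#' `prod_i [ w P_N(ac_i | class_i) + (1 - w) P_S(ac_i | mu_i, s_het) ]`,
#' a log-uniform prior on `s_het` and a uniform prior on `w` (the prior
#' misannotation weight). Each variant's `p_neutral` is the posterior
#' expectation of its neutral-component responsibility.
#'
#' @param variants Data frame of one gene's pLoF variants with columns `ac`
#'   (>= 1), `mu`, `class`, and optionally `variant_id`. Rows with `ac = 0`
#'   are rejected: the model is conditioned on observed variants.
#' @param neutral A [fit_neutral_sfs()] model.
#' @param n_chrom Chromosome sample size.
#' @param N_e Effective population size. Default 1e4. Note `4 N_e s_het` is
#'   the identified composite; `s_het` scales inversely with the assumed
#'   `N_e`.
#' @param s_grid Grid over `s_het`. Default 40 log-spaced points in
#'   \[1e-4, 1\].
#' @param w_grid Grid over `w`. Default 41 uniform points in \[0, 1\]
#'   (fine enough that refining the grid moves no `p_neutral` by more than
#'   0.01).
#' @return Object of class `pneutral_fit`: `posterior` (matrix s x w),
#'   `s_grid`, `w_grid`, `s_het_mean` (posterior mean), `log10_s_mean`,
#'   `w_mean`, and `variants` with a `p_neutral` column.
#' @export
fit_gene_mixture <- function(variants, neutral, n_chrom, N_e = 1e4,
                             s_grid = exp(seq(log(1e-4), log(1),
                                              length.out = 40L)),
                             w_grid = seq(0, 1, length.out = 41L)) {
  if (!nrow(variants)) stop("no pLoF variants supplied")
  if (any(variants$ac < 1)) {
    stop("all variants must have AC >= 1 (the mixture is conditioned on ",
         "observed variants)")
  }
  p_n <- neutral_pmf(neutral, variants$ac, variants$class)
  # n_variants x n_s matrix of selection pmfs
  p_s <- vapply(s_grid, function(s) {
    selection_pmf(variants$ac, variants$mu, s, n_chrom, N_e)
  }, numeric(nrow(variants)))
  p_s <- matrix(p_s, nrow = nrow(variants))

  n_s <- length(s_grid)
  n_w <- length(w_grid)
  log_post <- matrix(0, n_s, n_w)
  for (j in seq_len(n_w)) {
    w <- w_grid[j]
    mix <- w * p_n + (1 - w) * p_s  # recycles p_n down columns
    log_post[, j] <- colSums(log(pmax(mix, 1e-300)))
  }
  # log-uniform prior on s: uniform over the log-spaced grid; uniform on w
  log_post <- log_post - max(log_post)
  post <- exp(log_post)
  post <- post / sum(post)

  # p_neutral_i = E_post[ w P_N / (w P_N + (1-w) P_S) ]
  p_neutral <- numeric(nrow(variants))
  for (j in seq_len(n_w)) {
    w <- w_grid[j]
    num <- w * p_n
    resp <- num / pmax(num + (1 - w) * p_s, 1e-300)  # variants x s
    p_neutral <- p_neutral + resp %*% post[, j]
  }
  variants$p_neutral <- as.numeric(p_neutral)

  s_marg <- rowSums(post)
  structure(
    list(
      posterior = post,
      s_grid = s_grid,
      w_grid = w_grid,
      s_het_mean = sum(s_marg * s_grid),
      log10_s_mean = sum(s_marg * log10(s_grid)),
      w_mean = sum(colSums(post) * w_grid),
      variants = variants
    ),
    class = "pneutral_fit"
  )
}

#' @export
print.pneutral_fit <- function(x, ...) {
  cat(sprintf(
    "<pneutral_fit> %d variants; posterior mean s_het = %.4g, w = %.3f\n",
    nrow(x$variants), x$s_het_mean, x$w_mean
  ))
  invisible(x)
}

#' Fit the mixture across all genes of a variant table
#'
#' @param variants Variant data frame; pLoF rows (`stop_gained`,
#'   `splice_donor`, `splice_acceptor`) with `ac >= 1` are modelled per
#'   `gene_id`.
#' @param neutral A [fit_neutral_sfs()] model.
#' @inheritParams fit_gene_mixture
#' @return List with `fits` (named by gene) and `variants` (all modelled
#'   rows with `p_neutral` and the gene's posterior-mean `s_het`).
#' @export
fit_pneutral <- function(variants, neutral, n_chrom, N_e = 1e4, ...) {
  plof <- variants[variants$consequence %in%
                     c("stop_gained", "splice_donor", "splice_acceptor") &
                     variants$ac >= 1, , drop = FALSE]
  if (!nrow(plof)) stop("no observed pLoF variants")
  fits <- lapply(split(plof, plof$gene_id), function(v) {
    fit_gene_mixture(v, neutral, n_chrom, N_e, ...)
  })
  out <- do.call(rbind, lapply(names(fits), function(g) {
    v <- fits[[g]]$variants
    v$s_het_mean <- fits[[g]]$s_het_mean
    v
  }))
  rownames(out) <- NULL
  list(fits = fits, variants = out)
}

#' Flag neutral-like variants
#'
#' @param p_neutral Numeric vector of posterior neutral probabilities.
#' @param threshold Flag when `p_neutral > threshold`. Default 0.8.
#' @return Logical vector.
#' @export
classify_neutral <- function(p_neutral, threshold = 0.8) {
  p_neutral > threshold
}
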
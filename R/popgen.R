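# Shared mutation-selection-drift parameterisation.
#
# Under the gamma approximation to the equilibrium site frequency spectrum,
# the population frequency q of a deleterious allele at a site with mutation
# rate mu and heterozygous selection coefficient s is
#   q ~ Gamma(shape = 4 Ne mu, rate = 4 Ne s_eff),
# with the drift floor s_eff = max(s, 1/(2 Ne)) standing in for neutrality so
# a single family covers both regimes. Sampling n chromosomes with
# AC | q ~ Poisson(n q) makes the allele count marginally negative binomial:
#   AC ~ NB(size = 4 Ne mu, prob = b/(b + n)),  b = 4 Ne s_eff.

drift_floor <- function(N_e) 1 / (2 * N_e)

s_effective <- function(s_het, N_e) pmax(s_het, drift_floor(N_e))

nb_params <- function(mu, s_het, n_chrom, N_e) {
  b <- 4 * N_e * s_effective(s_het, N_e)
  list(size = 4 * N_e * mu, b = b, pi = n_chrom / (n_chrom + b))
}

#' Probability that a site is polymorphic in a sample
#'
#' Closed form for the probability that at least one copy of a variant with
#' mutation rate `mu` under heterozygous selection `s_het` is present among
#' `n_chrom` sampled chromosomes, under the gamma frequency spectrum with
#' effective population size `N_e`:
#' \deqn{P = 1 - (1 + n/(4 N_e s))^{-4 N_e \mu}}
#' (the gamma moment-generating function evaluated for the Poisson zero
#' class). Monotone increasing in `n_chrom` and `mu`, decreasing in `s_het`.
#' `s_het` below the drift floor `1/(2 N_e)` is clamped to it.
#'
#' @param s_het Heterozygous selection coefficient(s) in (0, 1].
#' @param mu Per-site per-generation mutation rate(s).
#' @param n_chrom Number of sampled chromosomes (2 x individuals for
#'   autosomes).
#' @param N_e Effective population size. Default 1e4.
#' @return Probability vector.
#' @export
#' @examples
#' prob_segregating(0.1, 2.5e-8, n_chrom = 2e6)
#' prob_segregating(1e-9, 2.5e-8, n_chrom = 2e6)  # at the drift floor
prob_segregating <- function(s_het, mu, n_chrom, N_e = 1e4) {
  if (!all(is.finite(s_het)) || !all(is.finite(mu)) ||
      !all(is.finite(n_chrom)) || !all(is.finite(N_e))) {
    stop("non-finite parameter")
  }
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(s_het <= 0)) stop("s_het must be positive")
  p <- nb_params(mu, s_het, n_chrom, N_e)
  # -expm1 of the log survival keeps precision when 4 Ne mu is tiny
  -expm1(-p$size * log1p(n_chrom / p$b))
}

#' Tabulate the site frequency spectrum by mutational class
#'
#' Counts variants per (mutational class, allele count) cell and records the
#' possible-site denominators per class. Rows with `ac = 0` contribute to the
#' denominators only. Mutational class is taken from a `class` column if
#' present, else derived from `context`/`alt`/`methylation` via
#' [classify_mutation()].
#'
#' @param variants Variant data frame ([read_variants_tsv()] layout). Should
#'   include every modelled site, observed or not, so that possible-site
#'   denominators are meaningful.
#' @param methyl_threshold Passed to [classify_mutation()] when the class has
#'   to be derived.
#' @return An object of class `sfs_table`: list with `counts` (data frame
#'   `class`, `ac`, `n_variants`) and `possible_sites` (named vector).
#' @export
build_sfs <- function(variants, methyl_threshold = 0.6) {
  cls <- if ("class" %in% names(variants)) {
    variants$class
  } else {
    classify_mutation(variants$context, variants$alt, variants$methylation,
                      methyl_threshold)
  }
  possible <- table(factor(cls, levels = MUTATION_CLASSES))
  seg <- variants$ac >= 1
  if (any(seg)) {
    counts <- as.data.frame(
      table(class = cls[seg], ac = variants$ac[seg]),
      responseName = "n_variants", stringsAsFactors = FALSE
    )
    counts$ac <- as.integer(as.character(counts$ac))
  } else {
    counts <- data.frame(class = character(0), ac = integer(0),
                         n_variants = integer(0))
  }
  counts <- counts[counts$n_variants > 0, , drop = FALSE]
  counts <- counts[order(counts$class, counts$ac), , drop = FALSE]
  rownames(counts) <- NULL
  structure(
    list(counts = counts,
         possible_sites = setNames(as.integer(possible), names(possible))),
    class = "sfs_table"
  )
}

#' Fraction of possible sites that are polymorphic, per mutational class
#'
#' Saturation = segregating sites / possible sites for each class. Classes
#' with zero possible sites are dropped with a warning.
#'
#' @param sfs An `sfs_table` from [build_sfs()].
#' @return Named numeric vector of saturation fractions in \[0, 1\].
#' @export
saturation_by_class <- function(sfs) {
  stopifnot(inherits(sfs, "sfs_table"))
  poss <- sfs$possible_sites
  empty <- names(poss)[poss == 0L]
  if (length(empty)) {
    warning("no possible sites in class(es): ",
            paste(empty, collapse = ", "), "; omitted", call. = FALSE)
    poss <- poss[poss > 0L]
  }
  seg <- tapply(sfs$counts$n_variants, sfs$counts$class, sum)
  out <- setNames(numeric(length(poss)), names(poss))
  out[names(seg)[names(seg) %in% names(out)]] <-
    seg[names(seg) %in% names(out)]
  out / poss
}

#' Infinite-sites recurrence rate from saturation
#'
#' With independent mutational origins arriving as a Poisson process of rate
#' `lambda` per site, a site is polymorphic unless it has zero observed
#' origins, so saturation = 1 - exp(-lambda) and
#' \deqn{\hat\lambda = -\ln(1 - \mathrm{saturation}).}
#'
#' @param saturation Fraction(s) of possible sites polymorphic, in \[0, 1).
#' @return Estimated expected observed origins per site.
#' @export
fit_recurrence_rate <- function(saturation) {
  stopifnot(all(saturation >= 0))
  if (any(saturation >= 1)) {
    stop("saturation of 1 leaves the recurrence rate unidentifiable")
  }
  -log1p(-saturation)
}

#' Recurrence model: Poisson origins with a per-origin allele-count law
#'
#' @param lambda_by_class Named non-negative vector of expected observed
#'   origins per site.
#' @param g Probability vector over per-origin allele counts k = 1, 2, ...;
#'   normalised internally. Default: `g(k)` proportional to `1/k` truncated
#'   at `k_max` (the neutral single-origin spectrum).
#' @param k_max Truncation for the default `g`. Default 10.
#' @return Object of class `recurrence_model`.
#' @export
recurrence_model <- function(lambda_by_class, g = NULL, k_max = 10L) {
  stopifnot(all(lambda_by_class >= 0))
  if (is.null(g)) g <- 1 / seq_len(k_max)
  stopifnot(all(g >= 0), sum(g) > 0)
  structure(
    list(lambda_by_class = lambda_by_class, g = g / sum(g)),
    class = "recurrence_model"
  )
}

#' Probability that a doubleton arose from two independent origins
#'
#' Under origins M ~ Poisson(lambda) with i.i.d. per-origin counts drawn from
#' `g`, an observed allele count of 2 arises either from a single origin seen
#' twice or from two origins each seen once:
#' \deqn{P(\mathrm{recurrent} \mid AC = 2)
#'   = \frac{\lambda g(1)^2}{2 g(2) + \lambda g(1)^2}.}
#' Monotone increasing in lambda.
#'
#' @param model A [recurrence_model()].
#' @param class Mutational class name (an entry of `lambda_by_class`).
#' @return Probability.
#' @export
#' @examples
#' m <- recurrence_model(c(methyl_cpg_transition = 0.1), g = c(0.5, 0.5))
#' prob_recurrent_doubleton(m, "methyl_cpg_transition")  # 0.0244
prob_recurrent_doubleton <- function(model, class) {
  stopifnot(inherits(model, "recurrence_model"))
  lam <- model$lambda_by_class[[class]]
  g1 <- model$g[1L]
  g2 <- if (length(model$g) >= 2L) model$g[2L] else 0
  if (g2 == 0 && lam == 0) {
    stop("doubleton probability undefined: g(2) = 0 and lambda = 0")
  }
  lam * g1^2 / (2 * g2 + lam * g1^2)
}

#' Analytic observed/expected ratio as a function of sample size
#'
#' Ratio of the probability of observing a variant under selection `s_het`
#' to the same probability at the drift floor, on a grid of sample sizes.
#' Starts below 1 for selected sites and converges to 1 as the sample grows,
#' reflecting that constraint metrics built from observed/expected counts are
#' sample-size dependent.
#'
#' @param s_het Heterozygous selection coefficient.
#' @param mu Mutation rate.
#' @param n_grid Vector of chromosome sample sizes.
#' @param N_e Effective population size.
#' @return Data frame with columns `n_chrom` and `oe`.
#' @export
expected_oe_curve <- function(s_het, mu, n_grid, N_e = 1e4) {
  num <- prob_segregating(s_het, mu, n_grid, N_e)
  den <- prob_segregating(drift_floor(N_e), mu, n_grid, N_e)
  data.frame(n_chrom = n_grid, oe = num / den)
}

#' Simulation-based power to detect constraint with LOEUF
#'
#' Simulates per-gene observed counts under a null and an alternative
#' selection strength (`o ~ Poisson(n_sites x prob_segregating)`), computes
#' the LOEUF upper bound for each replicate against the neutral expectation,
#' sets the critical value at the `alpha` quantile of the null LOEUF
#' distribution, and returns the fraction of alternative replicates falling
#' below it.
#'
#' @param s_null,s_alt Selection coefficients under the null and alternative.
#' @param mu Per-site mutation rate.
#' @param n_chrom Chromosome sample size.
#' @param n_sites Possible sites per gene.
#' @param alpha Test size. Default 0.05.
#' @param reps Monte Carlo replicates per hypothesis. Default 2000.
#' @param N_e Effective population size.
#' @param confidence LOEUF confidence level. Default 0.9.
#' @param seed Optional integer seed.
#' @return List with `power`, `critical_loeuf`, `alpha`, `reps`.
#' @export
loeuf_power <- function(s_null, s_alt, mu, n_chrom, n_sites,
                        alpha = 0.05, reps = 2000L, N_e = 1e4,
                        confidence = 0.9, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, reps >= 1)
  if (n_sites <= 0) stop("n_sites must be positive")
  if (!is.null(seed)) set.seed(seed)
  e_neutral <- n_sites * prob_segregating(drift_floor(N_e), mu, n_chrom, N_e)
  draw_loeuf <- function(s) {
    o <- rpois(reps, n_sites * prob_segregating(s, mu, n_chrom, N_e))
    loeuf_upper(o, e_neutral, confidence = confidence)
  }
  null_loeuf <- draw_loeuf(s_null)
  crit <- quantile(null_loeuf, probs = alpha, names = FALSE, type = 1)
  alt_loeuf <- draw_loeuf(s_alt)
  list(
    power = mean(alt_loeuf < crit),
    critical_loeuf = crit,
    alpha = alpha,
    reps = reps
  )
}
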
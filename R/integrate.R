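# Bayesian combination of literature-derived gene scores with constraint
# counts. The latent parameter is the depletion theta in [0, 1] of
# high-impact variation: the likelihood is o ~ Poisson(e (1 - theta)), and
# the literature percentile sets a beta prior on theta, so "higher = more
# clinically significant" holds for prior, likelihood and posterior alike.

#' OMELET configuration
#'
#' @param prior_strength Effective prior observations (beta concentration).
#'   Default 4.
#' @param grid_points Grid resolution over theta. Default 501.
#' @param credible Credible level whose lower bound is reported. Default
#'   0.95.
#' @param epsilon Floor/ceiling on the prior mean: the percentile is mapped
#'   to `epsilon + (1 - 2 epsilon) pct/100` so extreme percentiles keep a
#'   proper beta prior. Default 0.02.
#' @return Object of class `omelet_config`.
#' @export
omelet_config <- function(prior_strength = 4, grid_points = 501L,
                          credible = 0.95, epsilon = 0.02) {
  stopifnot(prior_strength > 0, grid_points >= 101L,
            credible > 0, credible < 1, epsilon >= 0, epsilon < 0.5)
  structure(
    list(prior_strength = prior_strength,
         grid_points = as.integer(grid_points),
         credible = credible, epsilon = epsilon),
    class = "omelet_config"
  )
}

omelet_prior_shapes <- function(prior_pct, config) {
  m <- config$epsilon + (1 - 2 * config$epsilon) * prior_pct / 100
  c(a = m * config$prior_strength, b = (1 - m) * config$prior_strength)
}

#' OMELET: posterior lower bound on constraint-literature depletion
#'
#' Combines a literature-derived percentile (as a beta prior on the
#' depletion theta of high-impact variation) with observed/expected
#' constraint counts (Poisson likelihood `o ~ Poisson(e (1 - theta))`) on a
#' grid over theta, and reports the lower bound of the posterior at the
#' configured credible level. The bound is non-decreasing in the prior
#' percentile for fixed counts and non-increasing in the observed count for
#' a fixed expectation.
#'
#' @param prior_pct Literature percentile(s) in \[0, 100\].
#' @param o Observed count(s).
#' @param e Expected count(s), positive.
#' @param config An [omelet_config()].
#' @return Data frame with `omelet` (the lower bound), `posterior_mean` and
#'   `posterior_median`, one row per input.
#' @export
#' @examples
#' omelet_score(95, o = 0, e = 50)   # strong joint evidence of depletion
#' omelet_score(50, o = 100, e = 100)  # data dominate towards no depletion
omelet_score <- function(prior_pct, o, e, config = omelet_config()) {
  stopifnot(inherits(config, "omelet_config"))
  n <- max(length(prior_pct), length(o), length(e))
  prior_pct <- rep_len(prior_pct, n)
  o <- rep_len(o, n)
  e <- rep_len(e, n)
  if (any(e <= 0)) stop("expected count must be positive")
  if (any(prior_pct < 0 | prior_pct > 100)) {
    stop("prior percentile must lie in [0, 100]")
  }
  # the grid carries exact beta prior masses per bin (robust to the
  # endpoint singularities of shapes below 1), modulated by the Poisson
  # likelihood at the bin midpoint; quantiles interpolate within a bin
  # proportionally to the prior, so they stay accurate for spiky priors
  k <- config$grid_points
  edges <- seq(0, 1, length.out = k + 1L)
  mids <- (edges[-1L] + edges[-(k + 1L)]) / 2
  out <- lapply(seq_len(n), function(i) {
    sh <- omelet_prior_shapes(prior_pct[i], config)
    prior_cdf <- pbeta(edges, sh["a"], sh["b"])
    prior_mass <- diff(prior_cdf)
    loglik <- dpois(o[i], e[i] * (1 - mids), log = TRUE)
    w <- prior_mass * exp(loglik - max(loglik))
    z <- sum(w)
    w <- w / z
    cdf <- cumsum(w)
    lik <- exp(loglik - max(loglik)) / z
    q <- function(p) {
      j <- findInterval(p, c(0, cdf), rightmost.closed = TRUE)
      j <- min(max(j, 1L), k)
      below <- if (j == 1L) 0 else cdf[j - 1L]
      target <- prior_cdf[j] + (p - below) / max(lik[j], 1e-300)
      qbeta(min(max(target, 0), 1), sh["a"], sh["b"])
    }
    # prior-weighted bin means keep the posterior mean exact under the
    # same piecewise-constant-likelihood approximation
    mean_num <- sh["a"] / (sh["a"] + sh["b"]) *
      diff(pbeta(edges, sh["a"] + 1, sh["b"]))
    data.frame(
      omelet = q(1 - config$credible),
      posterior_mean = sum(mean_num * exp(loglik - max(loglik))) / z,
      posterior_median = q(0.5)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Discovery Potential score
#'
#' Difference, in percentile points, between a gene's constraint percentile
#' (high = strongly constrained, i.e. the percentile rank of -LOEUF) and
#' its literature-derived loss-of-function impact percentile. Near zero
#' when the two agree; positive when constraint exceeds the literature
#' footprint (undiscovered biology); negative when literature evidence
#' exceeds constraint.
#'
#' @param constraint_pct Constraint percentile(s) in \[0, 100\].
#' @param pepper_llm_lof_pct Literature LoF-impact percentile(s).
#' @return Difference(s) in \[-100, 100\].
#' @export
dispo_score <- function(constraint_pct, pepper_llm_lof_pct) {
  stopifnot(
    all(constraint_pct >= 0 & constraint_pct <= 100),
    all(pepper_llm_lof_pct >= 0 & pepper_llm_lof_pct <= 100)
  )
  constraint_pct - pepper_llm_lof_pct
}

#' Percentile rank of the feature-minus-literature score difference
#'
#' Ranks `pepper_feat_pct - pepper_llm_pct` across the gene cohort and
#' returns the percentile rank (average-rank ties, `100 (rank - 0.5) / n`).
#' High values mark genes whose feature-predicted significance most exceeds
#' their literature-derived score, i.e. candidate understudied genes.
#'
#' @param pepper_feat_pct Feature-based percentile scores.
#' @param pepper_llm_pct Literature-derived percentile scores.
#' @return Percentile ranks in (0, 100).
#' @export
delta_pepper <- function(pepper_feat_pct, pepper_llm_pct) {
  stopifnot(length(pepper_feat_pct) == length(pepper_llm_pct))
  if (length(pepper_feat_pct) < 2L) {
    stop("need at least two genes to rank")
  }
  percentile_rank(pepper_feat_pct - pepper_llm_pct)
}

#' Flag candidate understudied disease genes
#'
#' Default rule: feature-based score percentile at or above `min_feat_pct`,
#' no established disease association, and a score-difference percentile
#' above `min_delta`.
#'
#' @param scores Gene score data frame with the columns named by the rule
#'   arguments (defaults: `pepper_feat_pct`, `has_disease_assoc`,
#'   `delta_pepper`).
#' @param min_feat_pct Minimum feature-based percentile. Default 95.
#' @param min_delta Minimum score-difference percentile (exclusive).
#'   Default 25.
#' @param require_no_disease Drop genes with an established disease
#'   association. Default TRUE.
#' @return Character vector of candidate `gene_id`s.
#' @export
flag_candidates <- function(scores, min_feat_pct = 95, min_delta = 25,
                            require_no_disease = TRUE) {
  need <- c("gene_id", "pepper_feat_pct", "delta_pepper")
  if (require_no_disease) need <- c(need, "has_disease_assoc")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    stop("missing column(s) required by the rule: ",
         paste(miss, collapse = ", "))
  }
  keep <- scores$pepper_feat_pct >= min_feat_pct &
    scores$delta_pepper > min_delta
  if (require_no_disease) keep <- keep & !scores$has_disease_assoc
  scores$gene_id[keep]
}
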
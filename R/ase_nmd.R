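# Beta-binomial mixture for allelic expression. Synonymous variants define
# a three-component background (balanced, monoallelic/extreme imbalance,
# random imbalance); pLoF variants are then fit with the background frozen
# plus one NMD component whose mean is constrained below 0.5, since
# nonsense-mediated decay depletes the transcript carrying the variant
# allele. Components are beta-binomial (not binomial) to absorb
# overdispersion from mapping bias and tissue mixing.

dbetabinom_log <- function(k, n, mean, concentration) {
  a <- mean * concentration
  b <- (1 - mean) * concentration
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# component log-density matrix builders; monoallelic is a symmetric
# two-sided pair sharing (mean, concentration)
component_logdens <- function(comp, par, alt, depth) {
  if (comp == "monoallelic") {
    l1 <- dbetabinom_log(alt, depth, par$mean, par$concentration)
    l2 <- dbetabinom_log(alt, depth, 1 - par$mean, par$concentration)
    m <- pmax(l1, l2)
    m + log(0.5 * exp(l1 - m) + 0.5 * exp(l2 - m))
  } else {
    dbetabinom_log(alt, depth, par$mean, par$concentration)
  }
}

# Box constraints per component; balanced and random imbalance share a
# fixed mean (the reference-bias offset) and are separated by their
# concentration ranges; the NMD mean is capped below 0.5.
component_bounds <- function(comp, balanced_mean) {
  switch(comp,
    balanced = list(
      mean = c(balanced_mean, balanced_mean), log_conc = log(c(50, 1e6))
    ),
    monoallelic = list(mean = c(0.002, 0.2), log_conc = log(c(5, 1e4))),
    random_imbalance = list(
      mean = c(balanced_mean, balanced_mean), log_conc = log(c(1, 50))
    ),
    nmd = list(mean = c(0.01, 0.45), log_conc = log(c(2, 1e4)))
  )
}

maximise_component <- function(comp, par, resp, alt, depth, balanced_mean) {
  bd <- component_bounds(comp, balanced_mean)
  obj <- function(theta) {
    p <- list(mean = theta[1L], concentration = exp(theta[2L]))
    -sum(resp * component_logdens(comp, p, alt, depth))
  }
  start <- c(
    min(max(par$mean, bd$mean[1L]), bd$mean[2L]),
    min(max(log(par$concentration), bd$log_conc[1L]), bd$log_conc[2L])
  )
  fit <- tryCatch(
    optim(start, obj, method = "L-BFGS-B",
          lower = c(bd$mean[1L], bd$log_conc[1L]),
          upper = c(bd$mean[2L], bd$log_conc[2L])),
    error = function(e) list(par = start, value = obj(start))
  )
  # generalized EM: keep the old parameters unless the update improves
  if (fit$value <= obj(start)) {
    list(mean = fit$par[1L], concentration = exp(fit$par[2L]))
  } else {
    par
  }
}

em_betabinom <- function(alt, depth, components, weights, free,
                         tol = 1e-6, max_iter = 200L, balanced_mean = 0.5) {
  n <- length(alt)
  comps <- names(components)
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ld <- vapply(comps, function(cm) {
      component_logdens(cm, components[[cm]], alt, depth)
    }, numeric(n))
    ld <- matrix(ld, nrow = n) + rep(log(pmax(weights, 1e-300)), each = n)
    m <- apply(ld, 1L, max)
    lik <- exp(ld - m)
    row_tot <- rowSums(lik)
    ll <- sum(m + log(row_tot))
    loglik_trace <- c(loglik_trace, ll)
    if (iter > 1L &&
        ll - loglik_trace[iter - 1L] < tol * max(1, abs(ll))) {
      converged <- TRUE
      resp <- lik / row_tot
      break
    }
    resp <- lik / row_tot
    weights <- colMeans(resp)
    for (j in seq_along(comps)) {
      if (free[j]) {
        components[[comps[j]]] <- maximise_component(
          comps[j], components[[comps[j]]], resp[, j], alt, depth,
          balanced_mean
        )
      }
    }
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  colnames(resp) <- comps
  structure(
    list(
      components = components,
      weights = setNames(as.numeric(weights), comps),
      posterior = resp,
      loglik_trace = loglik_trace,
      converged = converged
    ),
    class = "ase_mixture_fit"
  )
}

#' @export
print.ase_mixture_fit <- function(x, ...) {
  cat("<ase_mixture_fit>\n")
  for (cm in names(x$components)) {
    p <- x$components[[cm]]
    cat(sprintf("  %-17s w = %.3f  mean = %.3f  conc = %.1f\n",
                cm, x$weights[[cm]], p$mean, p$concentration))
  }
  cat(sprintf("  log-likelihood %.2f after %d iteration(s)%s\n",
              tail(x$loglik_trace, 1L), length(x$loglik_trace),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

default_background_init <- function(balanced_mean = 0.5) {
  list(
    balanced = list(mean = balanced_mean, concentration = 200),
    monoallelic = list(mean = 0.02, concentration = 50),
    random_imbalance = list(mean = balanced_mean, concentration = 4)
  )
}

#' Fit the three-component allelic-expression background
#'
#' Expectation-maximisation over component weights and parameters on
#' synonymous-variant read counts. The balanced component is constrained to
#' mean `balanced_mean` (default exactly 0.5; set slightly below to model
#' reference mapping bias) with high concentration; the monoallelic
#' component is a symmetric two-sided pair with extreme means; the random
#' imbalance component shares the balanced mean but has a free low
#' concentration. The log-likelihood is non-decreasing across iterations.
#'
#' @param ase Data frame with `ref_reads` and `alt_reads` (synonymous
#'   variants). Rows with zero depth are dropped with a warning.
#' @param init Optional initial component list (as
#'   `default_background_init()`).
#' @param tol Relative log-likelihood convergence tolerance. Default 1e-6.
#' @param max_iter Maximum EM iterations. Default 200.
#' @param balanced_mean Reference-bias offset for the balanced and
#'   random-imbalance means. Default 0.5.
#' @return An `ase_mixture_fit` with components `balanced`, `monoallelic`,
#'   `random_imbalance`.
#' @export
fit_ase_background <- function(ase, init = NULL, tol = 1e-6,
                               max_iter = 200L, balanced_mean = 0.5) {
  dat <- drop_zero_depth(ase)
  if (nrow(dat) < 100L) {
    stop("need at least 100 observations to fit the background")
  }
  components <- if (is.null(init)) {
    default_background_init(balanced_mean)
  } else {
    init
  }
  em_betabinom(
    dat$alt_reads, dat$ref_reads + dat$alt_reads,
    components, weights = rep(1 / 3, 3), free = rep(TRUE, 3),
    tol = tol, max_iter = max_iter, balanced_mean = balanced_mean
  )
}

#' Fit the NMD component over a frozen background
#'
#' Adds a fourth, NMD-driven depletion component (mean constrained below
#' 0.5, concentration free) to a background fit whose component parameters
#' stay frozen; EM runs over the four weights and the NMD parameters. The
#' per-variant posterior probability of the NMD component is the quantity
#' used downstream.
#'
#' @param ase Data frame with `ref_reads` and `alt_reads` (pLoF variants).
#' @param background An `ase_mixture_fit` from [fit_ase_background()].
#' @param nmd_init Initial NMD parameters. Default mean 0.2,
#'   concentration 20.
#' @inheritParams fit_ase_background
#' @return An `ase_mixture_fit` with the four components; `posterior[,
#'   "nmd"]` is the per-variant NMD probability.
#' @export
fit_ase_nmd <- function(ase, background,
                        nmd_init = list(mean = 0.2, concentration = 20),
                        tol = 1e-6, max_iter = 200L, balanced_mean = 0.5) {
  stopifnot(inherits(background, "ase_mixture_fit"))
  dat <- drop_zero_depth(ase)
  components <- c(background$components, list(nmd = nmd_init))
  w0 <- c(background$weights * 0.9, nmd = 0.1)
  em_betabinom(
    dat$alt_reads, dat$ref_reads + dat$alt_reads,
    components, weights = w0 / sum(w0),
    free = c(FALSE, FALSE, FALSE, TRUE),
    tol = tol, max_iter = max_iter, balanced_mean = balanced_mean
  )
}

drop_zero_depth <- function(ase) {
  stopifnot(all(c("ref_reads", "alt_reads") %in% names(ase)))
  depth <- ase$ref_reads + ase$alt_reads
  if (any(depth == 0)) {
    warning(sum(depth == 0), " zero-depth row(s) dropped", call. = FALSE)
    ase <- ase[depth > 0, , drop = FALSE]
  }
  ase
}

#' Geometric-mean separation ratio of NMD posteriors
#'
#' Ratio of the geometric mean posterior NMD probability for variants
#' classified as pLoF to that for variants classified as non-pLoF; higher
#' values mean the classification better separates variants by
#' NMD-consistent allelic imbalance. Posteriors are floored at `floor`
#' before taking logs.
#'
#' @param posteriors Per-variant posterior NMD probabilities.
#' @param is_plof Logical vector: predicted pLoF classification.
#' @param floor Lower floor applied before the log. Default 1e-6.
#' @return Ratio of geometric means (> 1 indicates separation).
#' @export
separation_ratio <- function(posteriors, is_plof, floor = 1e-6) {
  stopifnot(length(posteriors) == length(is_plof))
  if (!any(is_plof) || !any(!is_plof)) {
    stop("both the pLoF and the non-pLoF group must be non-empty")
  }
  lp <- log(pmax(posteriors, floor))
  exp(mean(lp[is_plof])) / exp(mean(lp[!is_plof]))
}
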
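#' Observed/expected ratio
#'
#' @param o Observed variant count(s), non-negative.
#' @param e Expected count(s) under neutrality, positive.
#' @return `o / e`.
#' @export
oe_ratio <- function(o, e) {
  if (any(e <= 0)) stop("expected count must be positive")
  if (any(o < 0)) stop("observed count must be non-negative")
  o / e
}

#' LOEUF: upper bound of the observed/expected ratio
#'
#' The upper limit of the exact two-sided Poisson confidence interval for the
#' mean at level `confidence`, divided by the expectation:
#' \deqn{\mathrm{LOEUF} = Q_{\Gamma}(1 - (1 - c)/2;\; o + 1, 1) / e.}
#' Lower values indicate stronger depletion of variation (constraint); the
#' bound shrinks as the expectation grows, so it is sample-size dependent by
#' construction.
#'
#' @inheritParams oe_ratio
#' @param confidence Two-sided confidence level in (0, 1). Default 0.90, so
#'   the reported bound is the 95th percentile of the Poisson-mean interval.
#' @return Upper bound(s); always at least `o / e`.
#' @export
#' @examples
#' loeuf_upper(0, 10)   # -log(0.05)/10 = 0.29957
#' loeuf_upper(10, 10)  # about 1.70
loeuf_upper <- function(o, e, confidence = 0.90) {
  if (any(e <= 0)) stop("expected count must be positive")
  stopifnot(confidence > 0, confidence < 1)
  qgamma(1 - (1 - confidence) / 2, shape = o + 1, rate = 1) / e
}

#' Flag the most deleterious missense variants exome-wide
#'
#' Computes, for each named predictor, the exome-wide score threshold at the
#' top `pct` percent of missense variants, and flags a variant if it reaches
#' the top slice for any predictor (union across predictors).
#'
#' @param variants Variant data frame; missense rows must carry one numeric
#'   column per predictor.
#' @param predictors Character vector of score column names. Higher scores =
#'   more deleterious.
#' @param pct Top percentage to flag per predictor. Default 1.
#' @return Logical vector along `variants` rows; `TRUE` only possible for
#'   missense rows.
#' @export
select_top_percentile <- function(variants, predictors, pct = 1) {
  stopifnot(pct > 0, pct <= 100)
  mis <- variants$consequence == "missense"
  flagged <- rep(FALSE, nrow(variants))
  for (p in predictors) {
    if (!p %in% names(variants)) {
      stop("missing predictor column: ", p)
    }
    sc <- variants[[p]]
    if (all(is.na(sc[mis]))) stop("all-missing score column: ", p)
    thr <- quantile(sc[mis], probs = 1 - pct / 100, na.rm = TRUE,
                    names = FALSE, type = 1)
    flagged <- flagged | (mis & !is.na(sc) & sc > thr)
  }
  flagged
}

#' LOEUF over pooled loss-of-function plus top-percentile missense counts
#'
#' Pools observed and expected counts across the pLoF class and the
#' top-percentile deleterious missense class, then applies [loeuf_upper()].
#' Pooling (rather than combining the two bounds) keeps the Poisson interval
#' exact; with an empty missense class it reduces to plain LOEUF.
#'
#' @param o_lof,e_lof Observed/expected pLoF counts.
#' @param o_mis,e_mis Observed/expected top-percentile missense counts.
#' @param confidence Confidence level, as in [loeuf_upper()].
#' @return Pooled upper bound(s).
#' @export
loeuf_mis <- function(o_lof, e_lof, o_mis = 0, e_mis = 0, confidence = 0.90) {
  loeuf_upper(o_lof + o_mis, e_lof + e_mis, confidence = confidence)
}

#' One-sided test that top missense variants are more depleted than pLoF
#'
#' Conditional on the total observed count, under equal depletion the
#' missense share is binomial with probability `e_mis / (e_mis + e_lof)`;
#' the p-value is the lower tail at the observed missense count. Small
#' values indicate the missense class is *more* constrained than the pLoF
#' class of the same gene.
#'
#' @param o_mis,e_mis Observed/expected top-percentile missense counts.
#' @param o_lof,e_lof Observed/expected pLoF counts.
#' @return p-value in (0, 1\]; 1 when nothing is observed in either class.
#' @export
#' @examples
#' missense_vs_plof_test(0, 10, 10, 10)  # 0.5^10
missense_vs_plof_test <- function(o_mis, e_mis, o_lof, e_lof) {
  if (any(e_mis <= 0) || any(e_lof <= 0)) {
    stop("expected counts must be positive in both classes")
  }
  total <- o_mis + o_lof
  p <- pbinom(o_mis, size = total, prob = e_mis / (e_mis + e_lof))
  ifelse(total == 0, 1, p)
}

#' Per-gene constraint table
#'
#' Convenience wrapper computing oe, LOEUF, LOEUF-MIS and the
#' missense-versus-pLoF comparison from a long gene-counts table.
#'
#' @param counts Data frame with columns `gene_id`, `class` (one of `plof`,
#'   `missense_top`, `synonymous`), `observed`, `expected`.
#' @param confidence Confidence level for the bounds.
#' @return Data frame with one row per gene: `gene_id`, `oe`, `loeuf`,
#'   `loeuf_mis`, `p_mis_vs_lof` (`NA` where a class is absent).
#' @export
constraint_table <- function(counts, confidence = 0.90) {
  need <- c("gene_id", "class", "observed", "expected")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  genes <- unique(counts$gene_id)
  rows <- lapply(genes, function(g) {
    sub <- counts[counts$gene_id == g, , drop = FALSE]
    get <- function(cl) sub[match(cl, sub$class), c("observed", "expected")]
    lof <- get("plof")
    mis <- get("missense_top")
    has_lof <- !is.na(lof$observed)
    has_mis <- !is.na(mis$observed)
    data.frame(
      gene_id = g,
      oe = if (has_lof) oe_ratio(lof$observed, lof$expected) else NA_real_,
      loeuf = if (has_lof) {
        loeuf_upper(lof$observed, lof$expected, confidence)
      } else NA_real_,
      loeuf_mis = if (has_lof && has_mis) {
        loeuf_mis(lof$observed, lof$expected, mis$observed, mis$expected,
                  confidence)
      } else NA_real_,
      p_mis_vs_lof = if (has_lof && has_mis) {
        missense_vs_plof_test(mis$observed, mis$expected,
                              lof$observed, lof$expected)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
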
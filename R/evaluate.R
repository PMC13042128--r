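#' Area under the precision-recall curve (average precision)
#'
#' Average-precision formulation: sum of precision times recall increment
#' over the score-sorted sequence, with tied scores grouped so the result
#' does not depend on the order within a tie. Constant scores therefore give
#' the prevalence exactly.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) labels; `TRUE` = positive.
#' @param higher_is_positive Direction of the score. Default TRUE.
#' @return List with `auprc` and `curve` (data frame `recall`,
#'   `precision`).
#' @export
auprc <- function(scores, labels, higher_is_positive = TRUE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L || n_pos == length(labels)) {
    stop("need at least one positive and one negative label")
  }
  if (!higher_is_positive) scores <- -scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group ties: cumulative counts at the end of each distinct-score block
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[block_end]
  n_at <- block_end
  precision <- tp / n_at
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  list(
    auprc = sum(precision * d_recall),
    curve = data.frame(recall = recall, precision = precision)
  )
}

#' Enrichment of a flag within a category, against matched permutations
#'
#' Bins genes by decile of a matching variable (for example LOEUF), then
#' draws permutation pseudo-categories with the same bin profile as the real
#' category. Enrichment is the observed flagged fraction in the category
#' divided by the mean flagged fraction over permutations; the p-value uses
#' the add-one convention so it can never be zero.
#'
#' @param flags Logical vector over genes.
#' @param in_category Logical vector: category membership.
#' @param matching Numeric matching variable over genes.
#' @param n_bins Number of matching bins. Default 10.
#' @param n_perm Permutations. Default 10000.
#' @param seed Integer seed. Default 1.
#' @return List with `enrichment`, `p_value`, `observed`, `n_perm`.
#' @export
matched_enrichment <- function(flags, in_category, matching,
                               n_bins = 10L, n_perm = 10000L, seed = 1L) {
  stopifnot(
    length(flags) == length(in_category),
    length(flags) == length(matching)
  )
  if (!any(in_category)) stop("category is empty")
  if (any(is.na(matching))) stop("matching values must be complete")
  set.seed(seed)
  qs <- quantile(matching, probs = seq(0, 1, length.out = n_bins + 1L),
                 names = FALSE)
  bin <- cut(matching, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  profile <- table(factor(bin[in_category], levels = sort(unique(bin))))
  obs <- mean(flags[in_category])

  by_bin <- split(seq_along(flags), bin)
  n_cat <- sum(in_category)
  perm_frac <- vapply(seq_len(n_perm), function(i) {
    idx <- unlist(lapply(names(profile), function(b) {
      k <- profile[[b]]
      if (k == 0L) return(integer(0))
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), k, replace = k > length(pool))]
    }), use.names = FALSE)
    sum(flags[idx]) / n_cat
  }, numeric(1))
  list(
    enrichment = obs / mean(perm_frac),
    p_value = (1 + sum(perm_frac >= obs)) / (n_perm + 1),
    observed = obs,
    n_perm = n_perm
  )
}

#' Fisher enrichment for a 2x2 table
#'
#' Odds ratio as the cross-product `(a d) / (b c)`, with the exact
#' hypergeometric p-value and the conditional maximum-likelihood 95%
#' confidence interval from [stats::fisher.test()]. A zero margin yields an
#' `NA` odds ratio with p = 1.
#'
#' @param a,b,c,d Cell counts: `a` = flagged in category, `b` = flagged
#'   outside, `c` = unflagged in category, `d` = unflagged outside.
#' @return List with `odds_ratio`, `p_value`, `conf_int`.
#' @export
#' @examples
#' fisher_enrichment(10, 90, 5, 895)  # OR = 19.89
fisher_enrichment <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1,
                conf_int = c(NA_real_, NA_real_)))
  }
  ft <- fisher.test(m)
  list(
    odds_ratio = (a * d) / (b * c),
    p_value = ft$p.value,
    conf_int = unname(ft$conf.int)
  )
}

#' Tissue-specific expression flags
#'
#' A gene is flagged in a tissue when its expression there reaches that
#' tissue's `pct`th percentile while the median of its expression across
#' all the other tissues stays below the `pct`th percentile of that
#' median's distribution, excluding broadly expressed genes.
#'
#' @param expr Numeric matrix, genes x tissues (rownames = gene ids).
#' @param pct Percentile threshold. Default 90.
#' @return Logical matrix of the same shape.
#' @export
tissue_specific_flags <- function(expr, pct = 90) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least two tissues")
  flags <- matrix(FALSE, nrow(expr), ncol(expr),
                  dimnames = dimnames(expr))
  p <- pct / 100
  for (t in seq_len(ncol(expr))) {
    thr_t <- quantile(expr[, t], probs = p, names = FALSE)
    med_others <- apply(expr[, -t, drop = FALSE], 1L, median)
    thr_med <- quantile(med_others, probs = p, names = FALSE)
    flags[, t] <- expr[, t] >= thr_t & med_others < thr_med
  }
  flags
}
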
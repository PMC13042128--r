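# NMD-informed rule engine for loss-of-function classification. Features
# are computed from transcript geometry, thresholds are either supplied or
# calibrated against 1 - p_neutral curves, and each variant is classified
# high-confidence (HC) or low-confidence (LC) in a relaxed and a strict
# mode; strict only ever removes variants from HC.

#' Threshold set for loss-of-function classification
#'
#' Defaults are runnable placeholders; the recommended path is to derive
#' thresholds from data with [calibrate_threshold()]. Strict thresholds must
#' be at least as exclusive as relaxed ones.
#'
#' @param junction_nt Stop-gained variants at most this many nt upstream of
#'   the final exon-exon junction are taken to escape NMD. Default 50, the
#'   canonical NMD rule.
#' @param cds_start_relaxed,cds_start_strict Stop-gained variants closer
#'   than this to the CDS start are low confidence. Defaults 100 / 150.
#' @param single_exon_end_nt Single-exon stop-gained variants within this
#'   distance of the transcript end are low confidence. Default 1000.
#' @param single_exon_start_relaxed,single_exon_start_strict CDS-start
#'   windows for single-exon transcripts. Defaults 100 / 150.
#' @param splice_relaxed,splice_strict Minimum splicing-impact score for a
#'   high-confidence splice variant. Defaults 0.2 / 0.5.
#' @return Object of class `loftee2_thresholds`.
#' @export
loftee2_thresholds <- function(junction_nt = 50,
                               cds_start_relaxed = 100,
                               cds_start_strict = 150,
                               single_exon_end_nt = 1000,
                               single_exon_start_relaxed = 100,
                               single_exon_start_strict = 150,
                               splice_relaxed = 0.2,
                               splice_strict = 0.5) {
  if (cds_start_strict < cds_start_relaxed ||
      single_exon_start_strict < single_exon_start_relaxed ||
      splice_strict < splice_relaxed) {
    stop("strict thresholds must be at least as exclusive as relaxed ones")
  }
  structure(
    list(
      junction_nt = junction_nt,
      cds_start_relaxed = cds_start_relaxed,
      cds_start_strict = cds_start_strict,
      single_exon_end_nt = single_exon_end_nt,
      single_exon_start_relaxed = single_exon_start_relaxed,
      single_exon_start_strict = single_exon_start_strict,
      splice_relaxed = splice_relaxed,
      splice_strict = splice_strict
    ),
    class = "loftee2_thresholds"
  )
}

#' Compute classification features for pLoF variants
#'
#' For every variant row, looks up its transcript and records the distance
#' to the last exon-exon junction (`NA` for single-exon models), the
#' CDS-start distance, the single-exon flag, the distance to the transcript
#' end, and the splicing-impact score for splice variants. Inapplicable
#' features are explicitly `NA`.
#'
#' @param variants Variant data frame with `transcript_id`, `pos`,
#'   `consequence`, and (for splice variants) `splice_score`.
#' @param transcripts Named list of [transcript_model()] objects.
#' @return Data frame of features aligned with `variants` rows.
#' @export
compute_features <- function(variants, transcripts) {
  missing_tx <- setdiff(unique(variants$transcript_id), names(transcripts))
  if (length(missing_tx)) {
    stop("transcript(s) not found: ", paste(missing_tx, collapse = ", "))
  }
  n <- nrow(variants)
  out <- data.frame(
    variant_id = if ("variant_id" %in% names(variants)) {
      variants$variant_id
    } else {
      sprintf("v%06d", seq_len(n))
    },
    consequence = variants$consequence,
    junction_dist = rep(NA_integer_, n),
    cds_start_dist = rep(NA_integer_, n),
    single_exon = rep(NA, n),
    end_dist = rep(NA_integer_, n),
    splice_score = if ("splice_score" %in% names(variants)) {
      variants$splice_score
    } else {
      rep(NA_real_, n)
    },
    stringsAsFactors = FALSE
  )
  for (tid in unique(variants$transcript_id)) {
    tx <- transcripts[[tid]]
    idx <- which(variants$transcript_id == tid)
    pos <- variants$pos[idx] - 1L  # table positions are 1-based
    m <- to_mrna_coord(tx, pos)
    if (any(!m$exonic & variants$consequence[idx] == "stop_gained")) {
      stop("stop-gained variant outside the exons of ", tid)
    }
    out$single_exon[idx] <- length(tx$exon_starts) == 1L
    out$junction_dist[idx] <- junction_distance(tx, pos)
    out$cds_start_dist[idx] <- m$cds_offset
    out$end_dist[idx] <- spliced_length(tx) - 1L - m$mrna_offset
  }
  out
}

#' Calibrate a feature threshold against 1 - p_neutral
#'
#' Sorts variants by the feature, computes the running (cumulative) mean of
#' `1 - p_neutral`, and locates a single changepoint by least-squares
#' segmentation of the per-variant `1 - p_neutral` sequence: the split
#' minimising the pooled within-segment sum of squares. The threshold is the
#' feature value at the last point of the lower segment. Significance of the
#' variance-explained gain is assessed by permuting `p_neutral` over the
#' sorted features; a non-significant gain returns an `NA` threshold.
#'
#' @param feature Numeric feature values (e.g. junction distance).
#' @param p_neutral Posterior neutral probabilities, aligned with `feature`.
#' @param n_perm Permutations for the significance gate. Default 1000.
#' @param alpha Significance level for the gate. Default 0.05.
#' @param min_seg Minimum points per segment. Default 10.
#' @param seed Integer seed for the permutation draw. Default 1.
#' @return Object of class `threshold_calibration`: `threshold` (`NA` if the
#'   gate fails), `gain`, `p_value`, and `curve` (data frame of sorted
#'   feature values and the cumulative mean of `1 - p_neutral`).
#' @export
calibrate_threshold <- function(feature, p_neutral, n_perm = 1000L,
                                alpha = 0.05, min_seg = 10L, seed = 1L) {
  keep <- !is.na(feature) & !is.na(p_neutral)
  feature <- feature[keep]
  p_neutral <- p_neutral[keep]
  n <- length(feature)
  if (n < 2L * min_seg) stop("too few variants to calibrate (", n, ")")
  if (length(unique(feature)) < 2L) {
    stop("constant feature: no threshold to calibrate")
  }
  ord <- order(feature)
  x <- feature[ord]
  y <- 1 - p_neutral[ord]

  split_gain <- function(y) {
    n <- length(y)
    cs <- cumsum(y)
    cs2 <- cumsum(y^2)
    k <- seq(min_seg, n - min_seg)
    sse_left <- cs2[k] - cs[k]^2 / k
    sse_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    sse_total <- cs2[n] - cs[n]^2 / n
    gain <- sse_total - (sse_left + sse_right)
    list(k = k[which.max(gain)], gain = max(gain))
  }
  obs <- split_gain(y)

  set.seed(seed)
  perm_gain <- vapply(seq_len(n_perm), function(i) {
    split_gain(sample(y))$gain
  }, numeric(1))
  p_value <- (1 + sum(perm_gain >= obs$gain)) / (n_perm + 1)

  curve <- data.frame(feature = x, cum_mean = cumsum(y) / seq_len(n))
  structure(
    list(
      threshold = if (p_value <= alpha) x[obs$k] else NA_real_,
      changepoint_index = obs$k,
      gain = obs$gain,
      p_value = p_value,
      curve = curve
    ),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold_calibration> threshold = %s (gain %.3g, p = %.3g)\n",
    format(x$threshold), x$gain, x$p_value
  ))
  invisible(x)
}

#' Classify pLoF variants in relaxed or strict mode
#'
#' Applies the rule set to a feature table. Stop-gained variants are low
#' confidence (LC) when the junction distance is at most `junction_nt`
#' (NMD escape) or the CDS-start distance is below the mode's window;
#' single-exon stop-gained variants when within `single_exon_end_nt` of the
#' transcript end or inside the mode's start window; splice variants when
#' the splicing-impact score is below the mode's threshold. Everything else
#' is high confidence (HC). A variant missing a feature its rules need is
#' classified `unscorable`, never silently HC. Every LC call carries at
#' least one named flag.
#'
#' @param features Feature table from [compute_features()].
#' @param thresholds A [loftee2_thresholds()].
#' @param mode `"relaxed"` or `"strict"`.
#' @return `features` with added columns `classification` (`HC`, `LC` or
#'   `unscorable`) and `flags` (comma-separated).
#' @export
annotate_loftee2 <- function(features, thresholds = loftee2_thresholds(),
                             mode = c("relaxed", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(thresholds, "loftee2_thresholds"))
  th <- thresholds
  cds_start_th <- if (mode == "strict") th$cds_start_strict else th$cds_start_relaxed
  se_start_th <- if (mode == "strict") th$single_exon_start_strict else th$single_exon_start_relaxed
  splice_th <- if (mode == "strict") th$splice_strict else th$splice_relaxed

  n <- nrow(features)
  cls <- rep("HC", n)
  flags <- vector("list", n)
  add_flag <- function(idx, flag) {
    for (i in idx) flags[[i]] <<- c(flags[[i]], flag)
  }

  stop_gained <- features$consequence == "stop_gained"
  splice <- features$consequence %in% c("splice_donor", "splice_acceptor")

  multi <- stop_gained & !is.na(features$single_exon) & !features$single_exon
  single <- stop_gained & !is.na(features$single_exon) & features$single_exon

  unscorable <- (stop_gained & (is.na(features$single_exon) |
                                  is.na(features$cds_start_dist) |
                                  (multi & is.na(features$junction_dist)) |
                                  (single & is.na(features$end_dist)))) |
    (splice & is.na(features$splice_score))

  esc <- multi & !unscorable & features$junction_dist <= th$junction_nt
  cls[esc] <- "LC"; add_flag(which(esc), "NMD_ESCAPE")

  near_start <- stop_gained & !unscorable &
    features$cds_start_dist < ifelse(single, se_start_th, cds_start_th)
  cls[near_start] <- "LC"; add_flag(which(near_start), "NEAR_CDS_START")

  se_end <- single & !unscorable & features$end_dist <= th$single_exon_end_nt
  cls[se_end] <- "LC"; add_flag(which(se_end), "SINGLE_EXON_NEAR_END")

  weak_splice <- splice & !unscorable & features$splice_score < splice_th
  cls[weak_splice] <- "LC"; add_flag(which(weak_splice), "WEAK_SPLICE_IMPACT")

  cls[unscorable] <- "unscorable"
  features$classification <- cls
  features$flags <- vapply(flags, function(f) {
    if (is.null(f)) "" else paste(f, collapse = ",")
  }, character(1))
  features$mode <- mode
  features
}

#' Precision, recall and F-beta against a truth set
#'
#' Variants classified HC form the predicted pLoF set; truth labels mark
#' genuine loss of function. Confidence intervals come from a case
#' bootstrap.
#'
#' @param classification Character vector (`HC` / `LC` / `unscorable`).
#' @param truth Logical vector: `TRUE` for genuine LoF.
#' @param beta F-measure weight; 0.5 emphasises precision. Default 0.5.
#' @param n_boot Bootstrap replicates. Default 2000.
#' @param seed Integer seed. Default 1.
#' @return List with `precision`, `recall`, `f_beta` and a `ci` matrix of
#'   bootstrap 95% intervals. With an empty HC set, precision and `f_beta`
#'   are `NA`.
#' @export
evaluate_truthset <- function(classification, truth, beta = 0.5,
                              n_boot = 2000L, seed = 1L) {
  stopifnot(length(classification) == length(truth))
  prf <- function(cls, tr) {
    pred <- cls == "HC"
    tp <- sum(pred & tr)
    prec <- if (sum(pred)) tp / sum(pred) else NA_real_
    rec <- if (sum(tr)) tp / sum(tr) else NA_real_
    f <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
      (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
    } else {
      NA_real_
    }
    c(precision = prec, recall = rec, f_beta = f)
  }
  est <- prf(classification, truth)
  set.seed(seed)
  n <- length(truth)
  boots <- t(vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    prf(classification[idx], truth[idx])
  }, numeric(3)))
  ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(
    precision = unname(est["precision"]),
    recall = unname(est["recall"]),
    f_beta = unname(est["f_beta"]),
    beta = beta,
    ci = ci
  )
}
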
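two_exon_tx <- function() {
  transcript_model("tx1", "g1", "+", c(0, 1000), c(900, 1501),
                   cds_start = 0, cds_end = 1501)
}

test_that("feature computation covers geometry and pass-through scores", {
  tx <- two_exon_tx()
  single <- transcript_model("tx2", "g2", "+", 2000, 3200,
                             cds_start = 2000, cds_end = 3200)
  v <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    transcript_id = c("tx1", "tx1", "tx2", "tx1"),
    pos = c(501L, 1101L, 3101L, 101L),  # 1-based table positions
    consequence = c("stop_gained", "stop_gained", "stop_gained",
                    "splice_donor"),
    splice_score = c(NA, NA, NA, 0.9),
    stringsAsFactors = FALSE
  )
  f <- compute_features(v, list(tx1 = tx, tx2 = single))
  # junction sits at mRNA offset 900; variant "a" at offset 500
  expect_equal(f$junction_dist, c(400L, -100L, NA, 800L))
  expect_equal(f$cds_start_dist[1:3], c(500L, 1000L, 1100L))
  expect_equal(f$single_exon, c(FALSE, FALSE, TRUE, FALSE))
  # single-exon stop 100 nt before transcript end
  expect_equal(f$end_dist[3], 99L)
  expect_equal(f$splice_score[4], 0.9)
  expect_error(compute_features(v, list(tx1 = tx)), "tx2")
})

test_that("a perfect step in p_neutral is recovered exactly", {
  feature <- c(seq(5, 50, by = 5), seq(55, 200, by = 5))
  p_neutral <- ifelse(feature <= 50, 1, 0)
  cal <- calibrate_threshold(feature, p_neutral, n_perm = 200)
  expect_equal(cal$threshold, 50)
  expect_lt(cal$p_value, 0.05)
  # cumulative curve starts at 0 (all escape) and rises past the step
  expect_equal(cal$curve$cum_mean[1], 0)
  expect_gt(tail(cal$curve$cum_mean, 1), 0.7)
})

test_that("pure-noise p_neutral yields no threshold; calibration is deterministic", {
  set.seed(6)
  feature <- runif(400, 0, 200)
  p_neutral <- runif(400)
  cal <- calibrate_threshold(feature, p_neutral, n_perm = 500)
  expect_true(is.na(cal$threshold))
  cal2 <- calibrate_threshold(feature, p_neutral, n_perm = 500)
  expect_identical(cal, cal2)
  expect_error(calibrate_threshold(rep(1, 400), p_neutral), "constant")
  expect_error(calibrate_threshold(feature[1:5], p_neutral[1:5]), "too few")
})

test_that("rule engine classifies by mode with named flags", {
  th <- loftee2_thresholds()
  f <- data.frame(
    variant_id = sprintf("v%d", 1:7),
    consequence = c("stop_gained", "stop_gained", "stop_gained",
                    "stop_gained", "splice_donor", "splice_donor",
                    "splice_acceptor"),
    junction_dist = c(40L, 200L, 200L, NA, NA, NA, NA),
    cds_start_dist = c(500L, 500L, 120L, 500L, NA, NA, NA),
    single_exon = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    end_dist = c(NA, NA, NA, NA, NA, NA, NA),
    splice_score = c(NA, NA, NA, NA, 0.35, 0.9, NA),
    stringsAsFactors = FALSE
  )
  relaxed <- annotate_loftee2(f, th, "relaxed")
  strict <- annotate_loftee2(f, th, "strict")
  # NMD escape in both modes, with the flag attached
  expect_equal(relaxed$classification[1], "LC")
  expect_match(relaxed$flags[1], "NMD_ESCAPE")
  expect_equal(strict$classification[1], "LC")
  # clean multi-exon stop: HC in both modes
  expect_equal(relaxed$classification[2], "HC")
  expect_equal(strict$classification[2], "HC")
  # CDS-start distance between relaxed (100) and strict (150) thresholds
  expect_equal(relaxed$classification[3], "HC")
  expect_equal(strict$classification[3], "LC")
  # missing junction feature on a multi-exon stop: unscorable, never HC
  expect_equal(relaxed$classification[4], "unscorable")
  # splice score between relaxed (0.2) and strict (0.5) thresholds
  expect_equal(relaxed$classification[5], "HC")
  expect_equal(strict$classification[5], "LC")
  expect_match(strict$flags[5], "WEAK_SPLICE_IMPACT")
  expect_equal(relaxed$classification[6], "HC")
  # splice variant with no score: unscorable
  expect_equal(relaxed$classification[7], "unscorable")
  # every LC carries at least one flag
  for (ann in list(relaxed, strict)) {
    expect_true(all(nchar(ann$flags[ann$classification == "LC"]) > 0))
  }
})

test_that("single-exon rules use end and start windows", {
  th <- loftee2_thresholds()
  f <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    consequence = "stop_gained",
    junction_dist = NA_integer_,
    cds_start_dist = c(2000L, 120L, 2000L),
    single_exon = TRUE,
    end_dist = c(500L, 5000L, 5000L),
    splice_score = NA_real_,
    stringsAsFactors = FALSE
  )
  relaxed <- annotate_loftee2(f, th, "relaxed")
  strict <- annotate_loftee2(f, th, "strict")
  expect_equal(relaxed$classification, c("LC", "HC", "HC"))
  expect_match(relaxed$flags[1], "SINGLE_EXON_NEAR_END")
  expect_equal(strict$classification, c("LC", "LC", "HC"))
})

test_that("strict mode never adds variants to the high-confidence set", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 50
    f <- data.frame(
      variant_id = sprintf("v%d", 1:n),
      consequence = sample(c("stop_gained", "splice_donor"), n, TRUE),
      junction_dist = sample(c(NA, -50:300), n, TRUE),
      cds_start_dist = sample(0:400, n, TRUE),
      single_exon = sample(c(TRUE, FALSE), n, TRUE),
      end_dist = sample(0:3000, n, TRUE),
      splice_score = runif(n),
      stringsAsFactors = FALSE
    )
    f$junction_dist[f$single_exon] <- NA
    hc_r <- annotate_loftee2(f, mode = "relaxed")$classification == "HC"
    hc_s <- annotate_loftee2(f, mode = "strict")$classification == "HC"
    expect_true(all(!hc_s | hc_r))  # HC(strict) subset of HC(relaxed)
  }
  expect_error(loftee2_thresholds(splice_relaxed = 0.6, splice_strict = 0.3),
               "exclusive")
})

test_that("truth-set evaluation returns exact precision/recall/F-beta", {
  cls <- c(rep("HC", 10), rep("LC", 10))
  truth <- c(rep(TRUE, 9), FALSE, rep(FALSE, 8), TRUE, TRUE)
  ev <- evaluate_truthset(cls, truth, n_boot = 200)
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 9 / 11)
  # the printed F with P = 0.90, R = 0.72 is 0.857
  f05 <- function(p, r) 1.25 * p * r / (0.25 * p + r)
  expect_equal(round(f05(0.90, 0.72), 3), 0.857)
  expect_equal(ev$f_beta, f05(0.9, 9 / 11))
  # perfect classifier
  ev2 <- evaluate_truthset(c("HC", "HC", "LC"), c(TRUE, TRUE, FALSE),
                           n_boot = 50)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$f_beta, 1)
  # empty HC set: undefined precision sentinel
  ev3 <- evaluate_truthset(c("LC", "LC"), c(TRUE, FALSE), n_boot = 50)
  expect_true(is.na(ev3$precision))
  # shuffled labels give precision near prevalence
  set.seed(8)
  cls_big <- sample(c("HC", "LC"), 4000, TRUE)
  truth_big <- sample(c(TRUE, FALSE), 4000, TRUE, prob = c(0.3, 0.7))
  ev4 <- evaluate_truthset(cls_big, truth_big, n_boot = 50)
  expect_lt(abs(ev4$precision - 0.3), 0.04)
})
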
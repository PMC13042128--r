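syn_table <- function(ac, class = "transversion") {
  data.frame(
    consequence = rep("synonymous", length(ac)), ac = ac,
    an = rep(1000L, length(ac)), class = rep_len(class, length(ac)),
    stringsAsFactors = FALSE
  )
}

test_that("neutral spectrum normalises, smooths and falls back when sparse", {
  # degenerate input: all singletons -> near point mass at AC 1
  m <- suppressWarnings(fit_neutral_sfs(syn_table(rep(1L, 5000)), 1000))
  expect_gt(neutral_pmf(m, 1, "transversion"), 0.95)
  for (cl in c("transversion", "methyl_cpg_transition")) {
    br <- m$breaks
    total <- sum(neutral_pmf(m, 1:1000, cl) *
                   1)  # per-AC probabilities over the full support
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # sparse classes fall back to pooled with a warning
  w <- capture_warnings(fit_neutral_sfs(syn_table(1:200), 1000))
  expect_true(any(grepl("pooled", w)))
  expect_error(fit_neutral_sfs(syn_table(integer(0)), 1000), "no observed")
})

test_that("neutral spectrum fit recovers the simulator's neutral AC law", {
  # about 1e4 observed synonymous methyl-CpG variants
  cfg <- small_config(
    seed = 61, n_genes = 500L, exons_per_gene = c(6L, 8L),
    sites_per_gene = c(1000L, 1000L),
    s_het_distribution = list(family = "fixed", value = 1e-9),
    class_probs = c(methyl_cpg_transition = 1, unmethyl_cpg_transition = 0,
                    non_cpg_transition = 0, transversion = 0),
    consequence_probs = c(synonymous = 1, missense = 0, stop_gained = 0,
                          splice_donor = 0, splice_acceptor = 0)
  )
  ex <- simulate_exome(cfg)
  m <- suppressWarnings(fit_neutral_sfs(ex$variants, cfg$n_chrom))
  n_obs <- sum(ex$variants$ac >= 1)
  expect_gt(n_obs, 1e4)
  # total variation between the fitted bin masses and the true
  # (negative binomial) law aggregated over the same bins
  mu <- default_mutation_rates()[["methyl_cpg_transition"]]
  truth_ac <- selection_pmf(1:cfg$n_chrom, mu, 1e-9, cfg$n_chrom, cfg$N_e)
  bin <- findInterval(1:cfg$n_chrom, m$breaks$lower)
  truth_bin <- as.numeric(rowsum(truth_ac, bin))
  fitted_bin <- m$by_class[["methyl_cpg_transition"]]
  expect_lt(0.5 * sum(abs(truth_bin - fitted_bin)), 0.05)
})

test_that("selection pmf is a proper, quadrature-consistent distribution", {
  n_chrom <- 1000
  p <- selection_pmf(1:n_chrom, 1e-7, 0.01, n_chrom)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  # mass shifts to singletons under strong selection
  expect_gt(selection_pmf(1, 1e-8, 0.5, 2e5),
            selection_pmf(1, 1e-8, 0.001, 2e5))
  # quadrature oracle: P(AC = k) = int Gamma(q) Pois(k; n q) dq on a grid
  quad_pmf <- function(k, mu, s, n, N_e = 1e4) {
    a <- 4 * N_e * mu
    b <- 4 * N_e * max(s, 1 / (2 * N_e))
    g <- function(u) {
      q <- exp(u)
      dgamma(q, a, b) * q * dpois(k, n * q)
    }
    # the integrand is a Gamma(a + k, b + n) kernel; centre the window on
    # its mode to keep the quadrature from missing the peak
    u0 <- log((a + k) / (b + n))
    num <- integrate(g, u0 - 15, u0 + 15, rel.tol = 1e-11,
                     subdivisions = 2000L)$value
    g0 <- function(u) {
      q <- exp(u)
      dgamma(q, a, b) * q * (-expm1(-n * q))
    }
    den <- integrate(g0, -200, 20, rel.tol = 1e-11,
                     subdivisions = 2000L)$value
    num / den
  }
  grid <- expand.grid(k = c(1, 2, 5, 20, 100), mu = c(3e-9, 1.2e-7),
                      s = c(1e-3, 0.01, 0.1, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    expect_equal(
      selection_pmf(grid$k[i], grid$mu[i], grid$s[i], 2e5),
      quad_pmf(grid$k[i], grid$mu[i], grid$s[i], 2e5),
      tolerance = 1e-6
    )
  }
  expect_error(selection_pmf(0, 1e-8, 0.1, 1e5), "AC >= 1")
  expect_error(selection_pmf(1, -1e-8, 0.1, 1e5), "invalid")
})

test_that("gene mixture separates a frequency outlier from singletons", {
  set.seed(1)
  neutral <- suppressWarnings(
    fit_neutral_sfs(syn_table(pmax(1, rnbinom(2000, size = 0.2, mu = 60))),
                    1e5)
  )
  gene <- data.frame(
    ac = c(rep(1L, 12), 500L), mu = 1e-8, class = "transversion",
    stringsAsFactors = FALSE
  )
  fit <- fit_gene_mixture(gene, neutral, n_chrom = 1e5)
  expect_true(all(fit$variants$p_neutral >= 0 & fit$variants$p_neutral <= 1))
  expect_gt(fit$variants$p_neutral[13], 0.9)
  expect_true(all(fit$variants$p_neutral[1:12] < 0.5))
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-12)
  # forcing w = 0 forces every p_neutral to zero
  fit0 <- fit_gene_mixture(gene, neutral, n_chrom = 1e5, w_grid = 0)
  expect_equal(fit0$variants$p_neutral, rep(0, 13))
  # observed-variant conditioning
  expect_error(
    fit_gene_mixture(data.frame(ac = 0L, mu = 1e-8, class = "transversion"),
                     neutral, 1e5),
    "AC >= 1"
  )
})

test_that("grid posterior agrees with a 4x finer brute-force grid", {
  set.seed(2)
  neutral <- suppressWarnings(
    fit_neutral_sfs(syn_table(pmax(1, rnbinom(2000, size = 0.2, mu = 60))),
                    1e5)
  )
  gene <- data.frame(
    ac = c(1L, 1L, 3L, 8L, 150L), mu = c(1e-8, 3e-9, 1e-8, 6e-9, 1e-8),
    class = "transversion", stringsAsFactors = FALSE
  )
  coarse <- fit_gene_mixture(gene, neutral, n_chrom = 1e5)
  fine <- fit_gene_mixture(
    gene, neutral, n_chrom = 1e5,
    s_grid = exp(seq(log(1e-4), log(1), length.out = 160L)),
    w_grid = seq(0, 1, length.out = 164L)
  )
  expect_lt(max(abs(coarse$variants$p_neutral - fine$variants$p_neutral)),
            0.01)
})

test_that("p_neutral rises with allele count in constrained genes", {
  # smooth neutral spectrum: a systematic quantile sample of the drift-law
  # allele-count distribution, so the neutral/selected likelihood ratio is
  # monotone in AC across the full frequency range
  size <- 4e4 * 1e-8
  p0 <- dnbinom(0, size = size, mu = 40)
  qs <- p0 + (1 - p0) * (1:5000 - 0.5) / 5000
  acs <- pmax(1, qnbinom(qs, size = size, mu = 40))
  neutral <- suppressWarnings(fit_neutral_sfs(syn_table(acs), 2e5))
  gene <- data.frame(
    ac = c(1L, 2L, 5L, 20L, 80L, 400L), mu = 1e-8,
    class = "transversion", stringsAsFactors = FALSE
  )
  fit <- fit_gene_mixture(gene, neutral, n_chrom = 2e5)
  if (fit$s_het_mean > 10 / (2 * 1e4)) {
    expect_true(all(diff(fit$variants$p_neutral) >= -1e-9))
  }
})

test_that("neutral-like classification respects thresholds and bimodality", {
  p <- c(0.01, 0.3, 0.85, 0.99)
  expect_equal(classify_neutral(p, 1.0), rep(FALSE, 4))
  expect_equal(classify_neutral(p, 0.0), rep(TRUE, 4))
  expect_equal(classify_neutral(p), c(FALSE, FALSE, TRUE, TRUE))
  # bimodal distribution: flag fraction insensitive to threshold choice
  set.seed(4)
  bimodal <- c(rbeta(5000, 0.5, 20), rbeta(300, 20, 0.5))
  fr <- vapply(c(0.6, 0.7, 0.8, 0.9), function(t) mean(bimodal > t),
               numeric(1))
  expect_lt(max(fr) - min(fr), 0.01)
})
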
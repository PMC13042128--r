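test_that("prob_segregating matches gamma-Poisson quadrature on a grid", {
  grid <- expand.grid(
    s_het = c(1e-5, 1e-3, 0.01, 0.1, 0.5),
    mu = c(3e-9, 1.5e-8, 1.2e-7),
    n_chrom = c(1e3, 1e5, 2e6),
    N_e = c(1e4, 2e4)
  )
  p <- with(grid, prob_segregating(s_het, mu, n_chrom, N_e))
  q <- mapply(quad_prob_segregating, grid$s_het, grid$mu, grid$n_chrom,
              grid$N_e)
  expect_lt(max(abs(p - q)), 1e-6)
  # limits and monotonicity
  expect_equal(prob_segregating(0.1, 2.5e-8, 0), 0)
  expect_lt(prob_segregating(0.1, 1e-12, 2e6), 1e-4)
  expect_true(all(diff(prob_segregating(0.1, 2.5e-8, 10^(3:7))) > 0))
  expect_true(all(diff(prob_segregating(c(0.5, 0.1, 0.01), 2.5e-8, 2e6)) > 0))
  expect_error(prob_segregating(NaN, 1e-8, 1e5), "non-finite")
})

test_that("SFS tabulation and saturation handle full, empty and ordered cases", {
  v <- data.frame(
    context = c("ACG", "ACG", "AAT", "ACA", "ACG"),
    alt = c("T", "T", "G", "A", "T"),
    methylation = c(0.9, 0.9, 0, 0, 0.1),
    ac = c(2L, 0L, 1L, 1L, 1L),
    an = 100L
  )
  sfs <- build_sfs(v)
  expect_equal(unname(sfs$possible_sites[c("methyl_cpg_transition",
                                           "non_cpg_transition",
                                           "transversion")]),
               c(2L, 1L, 1L))
  sat <- saturation_by_class(sfs)
  expect_equal(unname(sat["methyl_cpg_transition"]), 0.5)
  expect_equal(unname(sat["non_cpg_transition"]), 1.0)
  # all observed -> 1; none observed -> 0
  v2 <- v; v2$ac <- 1L
  expect_true(all(saturation_by_class(build_sfs(v2)) == 1))
  v3 <- v; v3$ac <- 0L
  expect_true(all(saturation_by_class(build_sfs(v3)) == 0))
  # absent class omitted with warning
  expect_warning(saturation_by_class(build_sfs(v[1:2, ])), "omitted")
})

test_that("recurrence rate inverts Poisson-origins saturation", {
  expect_equal(fit_recurrence_rate(0), 0)
  expect_equal(fit_recurrence_rate(1 - exp(-1)), 1)
  expect_error(fit_recurrence_rate(1), "unidentifiable")
  # simulation recovery: sites with M ~ Poisson(0.5) origins
  set.seed(3)
  n_sites <- 2e5
  seg <- rpois(n_sites, 0.5) > 0
  lam_hat <- fit_recurrence_rate(mean(seg))
  se <- sd(seg) / sqrt(n_sites) / (1 - mean(seg))  # delta method
  expect_lt(abs(lam_hat - 0.5), 3 * se)
})

test_that("recurrent-doubleton probability matches enumeration over origins", {
  m <- recurrence_model(c(x = 0.1), g = c(0.5, 0.5))
  expect_equal(prob_recurrent_doubleton(m, "x"), 0.1 * 0.25 / (1 + 0.025),
               tolerance = 1e-12)
  expect_equal(round(prob_recurrent_doubleton(m, "x"), 4), 0.0244)

  # enumeration oracle over M <= 10 origins, g supported on {1, 2}
  enum_oracle <- function(lam, g1, g2) {
    p_two_single <- 0
    p_single_double <- 0
    for (M in 1:10) {
      pm <- dpois(M, lam)
      if (M == 1) p_single_double <- p_single_double + pm * g2
      if (M == 2) p_two_single <- p_two_single + pm * g1^2
    }
    p_two_single / (p_two_single + p_single_double)
  }
  for (lam in c(0.05, 0.5, 2)) {
    m <- recurrence_model(c(x = lam), g = c(0.7, 0.3))
    expect_equal(prob_recurrent_doubleton(m, "x"),
                 enum_oracle(lam, 0.7, 0.3), tolerance = 1e-12)
  }
  # limits
  expect_equal(prob_recurrent_doubleton(
    recurrence_model(c(x = 1e-12), g = c(0.5, 0.5)), "x"
  ), 0, tolerance = 1e-9)
  expect_equal(prob_recurrent_doubleton(
    recurrence_model(c(x = 0.3), g = c(1, 0)), "x"
  ), 1)
  expect_error(prob_recurrent_doubleton(
    recurrence_model(c(x = 0), g = c(1, 0)), "x"
  ), "undefined")
})

test_that("recurrent-doubleton estimate agrees with forward simulation", {
  set.seed(9)
  for (lam in c(0.05, 0.5, 2)) {
    g <- c(0.6, 0.4)
    n_sites <- 1e6
    M <- rpois(n_sites, lam)
    site <- rep.int(seq_len(n_sites), M)
    k <- sample(1:2, length(site), TRUE, prob = g)
    total <- integer(n_sites)
    agg <- rowsum(k, site)
    total[as.integer(rownames(agg))] <- agg[, 1L]
    recurrent <- M >= 2
    is_double <- total == 2L
    est <- mean(recurrent[is_double])
    se <- sqrt(est * (1 - est) / sum(is_double))
    m <- recurrence_model(c(x = lam), g = g)
    expect_lt(abs(prob_recurrent_doubleton(m, "x") - est), 3 * se)
  }
})

test_that("analytic obs/exp curves are bounded, monotone and ordered", {
  n_grid <- 10^seq(3, 7, by = 0.5)
  drift <- expected_oe_curve(1e-9, 2.5e-8, n_grid)
  expect_equal(drift$oe, rep(1, length(n_grid)))
  for (s in c(0.01, 0.1, 0.5)) {
    oe <- expected_oe_curve(s, 2.5e-8, n_grid)$oe
    expect_true(all(oe >= 0 & oe <= 1))
    expect_true(all(diff(oe) >= -1e-12))
  }
  # stronger selection sits below weaker at every n, slowly converging up
  strong <- expected_oe_curve(0.5, 2.5e-8, n_grid)$oe
  weak <- expected_oe_curve(0.01, 2.5e-8, n_grid)$oe
  expect_true(all(strong < weak))
  expect_gt(expected_oe_curve(0.01, 2.5e-8, 1e9)$oe,
            expected_oe_curve(0.01, 2.5e-8, 1e4)$oe)
})

test_that("LOEUF power has correct size, rising-regime gains and strong-selection limit", {
  # size: s_alt = s_null recovers alpha within Monte-Carlo error
  sz <- loeuf_power(0.01, 0.01, mu = 1e-7, n_chrom = 2e5, n_sites = 2000,
                    alpha = 0.05, reps = 4000, seed = 1)
  expect_lt(abs(sz$power - 0.05), 0.02)
  # near-complete power for strong selection at large n
  pw <- loeuf_power(1e-9, 0.5, mu = 1e-7, n_chrom = 2e6, n_sites = 2000,
                    reps = 2000, seed = 2)
  expect_gt(pw$power, 0.95)
  # sample-size gains while constrained genes remain unsaturated: power
  # rises with cohort size in the pre-saturation regime
  p_small <- loeuf_power(1e-9, 0.5, mu = 1e-8, n_chrom = 1e3,
                         n_sites = 1000, reps = 2000, seed = 3)$power
  p_large <- loeuf_power(1e-9, 0.5, mu = 1e-8, n_chrom = 1e4,
                         n_sites = 1000, reps = 2000, seed = 3)$power
  expect_gte(p_large, p_small)
  expect_error(loeuf_power(0.01, 0.1, 1e-8, 1e5, n_sites = 0), "n_sites")
})
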
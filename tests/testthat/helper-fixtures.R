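# Shared fixture builders; everything is generated in code at test time.

# brute-force spliced-transcript oracle: enumerate exonic genomic positions
# (0-based) in transcription order, base by base
splice_oracle <- function(tx) {
  pos <- unlist(lapply(seq_along(tx$exon_starts), function(i) {
    seq(tx$exon_starts[i], tx$exon_ends[i] - 1L)
  }))
  if (tx$strand == "-") pos <- rev(pos)
  pos  # pos[k] = 0-based genomic position of mRNA offset k-1
}

random_transcript <- function(max_exons = 6L) {
  n_ex <- sample.int(max_exons, 1L)
  lens <- sample(3:30, n_ex, replace = TRUE) * 3L
  gaps <- sample(10:100, n_ex, replace = TRUE)
  starts <- cumsum(c(sample(0:50, 1L), head(lens + gaps, -1L)))
  transcript_model(
    "txr", "gr", sample(c("+", "-"), 1L),
    exon_starts = starts, exon_ends = starts + lens,
    cds_start = starts[1L], cds_end = starts[n_ex] + lens[n_ex]
  )
}

small_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    n_genes = 30L, sites_per_gene = c(100L, 200L), n_samples = 5e4,
    seed = seed
  )
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# rank-based AUROC (Mann-Whitney statistic)
auprc_roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# quadrature oracle for the gamma-Poisson segregation probability:
# P(AC >= 1) = int Gamma(q; a, b) (1 - exp(-n q)) dq, integrated on the
# log-q scale to tame the q^(a-1) singularity at 0 for small shapes
quad_prob_segregating <- function(s_het, mu, n_chrom, N_e = 1e4) {
  s_eff <- max(s_het, 1 / (2 * N_e))
  a <- 4 * N_e * mu
  b <- 4 * N_e * s_eff
  g <- function(u) {
    q <- exp(u)
    dgamma(q, shape = a, rate = b) * q * (-expm1(-n_chrom * q))
  }
  stats::integrate(g, -200, 20, rel.tol = 1e-11, abs.tol = 1e-14,
                   subdivisions = 2000L)$value
}
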
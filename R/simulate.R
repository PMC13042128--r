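# Synthetic-exome generator. Allele counts are drawn from the same
# mutation-selection-drift model the analytic modules assume: at each site
# the number of observed mutational origins is
#   M ~ Poisson(lambda),  lambda = 4 Ne mu * log(1 + n/(4 Ne s_eff)),
# and each origin contributes an allele count from the logarithmic
# distribution with parameter pi = n/(n + 4 Ne s_eff). The compound is
# exactly the negative binomial NB(4 Ne mu, pi), i.e. the gamma frequency
# spectrum sampled with Poisson noise, so simulated saturation matches
# prob_segregating() and simulated AC distributions match selection_pmf()
# by construction while still carrying a per-site true origins count.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-exome generator with documented
#' defaults. The defaults describe a cohort of 1e5 individuals sampled from a
#' population of effective size 1e4, genes with per-gene selection drawn
#' log-uniformly over \[1e-3, 0.5\], 5% randomly misannotated pLoF sites plus
#' systematic NMD-escape misannotation inside the 50 nt window upstream of
#' the final junction and the 100 nt window after the CDS start.
#'
#' @param n_genes Number of genes. Default 100.
#' @param exons_per_gene Integer range (min, max). Default c(2, 8).
#' @param sites_per_gene Integer range of modelled sites per gene (possible
#'   variants, observed or not). Default c(150, 300).
#' @param n_samples Individuals in the cohort. Default 1e5 (autosomal
#'   chromosome count is twice this).
#' @param N_e Effective population size. Default 1e4.
#' @param s_het_distribution List: `family` `"loguniform"` with `min`/`max`
#'   in (0, 1\], or `"fixed"` with `value`.
#' @param misannotation_rate Fraction of pLoF sites outside the systematic
#'   escape windows that are assigned neutral frequencies. Default 0.05.
#' @param nmd_escape_window Stop-gained variants at most this many nt
#'   upstream of the final exon-exon junction escape NMD and are simulated
#'   as neutral. Default 50.
#' @param near_start_window Stop-gained variants closer than this to the CDS
#'   start escape full loss of function and are simulated as neutral.
#'   Default 100.
#' @param class_probs Named probabilities over mutational classes per site.
#' @param mutation_rates Named per-class mutation rates; default
#'   [default_mutation_rates()].
#' @param consequence_probs Named probabilities over consequence classes.
#' @param ase_depth_distribution List: `family` `"nbinom"` with `mean` and
#'   `size`. Default mean 50, size 2 (overdispersed RNA-seq coverage).
#' @param ase_components Named list of beta-binomial component parameters
#'   (`mean`, `concentration`) for `balanced`, `monoallelic`,
#'   `random_imbalance`, `nmd`.
#' @param score_noise_sd Percentile-point noise on literature scores.
#'   Default 10.
#' @param understudied_fraction Fraction of genes whose literature score is
#'   forced low regardless of selection. Default 0.1.
#' @param seed Integer seed; mandatory.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 100L,
                              exons_per_gene = c(2L, 8L),
                              sites_per_gene = c(150L, 300L),
                              n_samples = 1e5,
                              N_e = 1e4,
                              s_het_distribution = list(
                                family = "loguniform", min = 1e-3, max = 0.5
                              ),
                              misannotation_rate = 0.05,
                              nmd_escape_window = 50L,
                              near_start_window = 100L,
                              class_probs = c(
                                methyl_cpg_transition = 0.035,
                                unmethyl_cpg_transition = 0.035,
                                non_cpg_transition = 0.26,
                                transversion = 0.67
                              ),
                              mutation_rates = default_mutation_rates(),
                              consequence_probs = c(
                                synonymous = 0.40, missense = 0.40,
                                stop_gained = 0.15, splice_donor = 0.025,
                                splice_acceptor = 0.025
                              ),
                              ase_depth_distribution = list(
                                family = "nbinom", mean = 50, size = 2
                              ),
                              ase_components = list(
                                balanced = list(mean = 0.5, concentration = 200),
                                monoallelic = list(mean = 0.02, concentration = 50),
                                random_imbalance = list(mean = 0.5, concentration = 4),
                                nmd = list(mean = 0.2, concentration = 20)
                              ),
                              score_noise_sd = 10,
                              understudied_fraction = 0.1,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(
    misannotation_rate >= 0, misannotation_rate <= 1,
    understudied_fraction >= 0, understudied_fraction <= 1,
    abs(sum(class_probs) - 1) < 1e-8,
    abs(sum(consequence_probs) - 1) < 1e-8
  )
  if (s_het_distribution$family == "loguniform") {
    if (s_het_distribution$min <= 0 || s_het_distribution$max > 1) {
      stop("s_het distribution support must lie in (0, 1]")
    }
  } else if (s_het_distribution$family == "fixed") {
    if (s_het_distribution$value <= 0 || s_het_distribution$value > 1) {
      stop("s_het distribution support must lie in (0, 1]")
    }
  } else {
    stop("unknown s_het distribution family: ", s_het_distribution$family)
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      sites_per_gene = as.integer(sites_per_gene),
      n_samples = n_samples,
      n_chrom = 2 * n_samples,
      N_e = N_e,
      s_het_distribution = s_het_distribution,
      misannotation_rate = misannotation_rate,
      nmd_escape_window = as.integer(nmd_escape_window),
      near_start_window = as.integer(near_start_window),
      class_probs = class_probs,
      mutation_rates = mutation_rates,
      consequence_probs = consequence_probs,
      ase_depth_distribution = ase_depth_distribution,
      ase_components = ase_components,
      score_noise_sd = score_noise_sd,
      understudied_fraction = understudied_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

draw_s_het <- function(dist, n) {
  switch(dist$family,
    loguniform = exp(runif(n, log(dist$min), log(dist$max))),
    fixed = rep(dist$value, n)
  )
}

# Logarithmic(p) sampler (Kemp's LK algorithm), vectorised.
rlogarithmic <- function(n, p) {
  if (n == 0L) return(integer(0))
  u2 <- runif(n)
  out <- rep(1, n)
  idx <- which(u2 <= p)
  if (length(idx)) {
    u1 <- runif(length(idx))
    q <- -expm1(u1 * log1p(-p))  # 1 - (1-p)^u1
    k <- rep(2, length(idx))
    small <- u2[idx] < q^2
    # cap guards log(q) underflow at p ~ 1
    k[small] <- pmin(1e12, pmax(1, floor(1 + log(u2[idx][small]) / log(q[small]))))
    k[u2[idx] > q] <- 1
    out[idx] <- k
  }
  out
}

# Canonical (context, alt, methylation) triple reproducing each class under
# classify_mutation(); the simulator carries no genome sequence.
class_context <- function(cls) {
  map <- list(
    methyl_cpg_transition = c("ACG", "C", "T", "0.9"),
    unmethyl_cpg_transition = c("ACG", "C", "T", "0.1"),
    non_cpg_transition = c("AAT", "A", "G", "0"),
    transversion = c("ACA", "C", "A", "0")
  )
  m <- do.call(rbind, map[cls])
  data.frame(
    context = m[, 1L], ref = m[, 2L], alt = m[, 3L],
    methylation = as.numeric(m[, 4L]), stringsAsFactors = FALSE
  )
}

simulate_transcript <- function(gene_idx, n_exons) {
  # internal exons 120-240 nt, last exon longer (300-900 nt) as in real
  # genes; intron length fixed at 200; total spliced length padded to a
  # multiple of 3 and used entirely as CDS
  lens <- sample(40:80, n_exons, replace = TRUE) * 3L
  lens[n_exons] <- sample(100:300, 1L) * 3L
  starts <- integer(n_exons)
  offset <- (gene_idx - 1L) * 1000000L
  for (i in seq_len(n_exons)) {
    starts[i] <- offset
    offset <- offset + lens[i] + 200L
  }
  strand <- sample(c("+", "-"), 1L)
  transcript_model(
    sprintf("tx%04d", gene_idx), sprintf("g%04d", gene_idx), strand,
    exon_starts = starts, exon_ends = starts + lens,
    cds_start = starts[1L], cds_end = starts[n_exons] + lens[n_exons]
  )
}

#' Simulate a synthetic exome
#'
#' Generates transcripts, modelled sites (all possible variants of the
#' chosen classes, observed or not) and sampled allele counts under
#' mutation-selection-drift with recurrent mutation. Stop-gained sites
#' inside the NMD-escape window (at most `nmd_escape_window` nt upstream of
#' the final junction) or closer than `near_start_window` nt to the CDS
#' start, plus a random `misannotation_rate` fraction of the remaining pLoF
#' sites, are drawn with neutral frequencies and flagged as misannotated in
#' the truth table. Missense sites carry two correlated predictor score
#' columns (`pred_a`, `pred_b`); the most deleterious slice (latent
#' deleteriousness above 0.99) experiences the gene's selection, the rest
#' drift. Splice sites carry a `splice_score` coupled to their truth status.
#' Identical seeds give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_exome`: list with `transcripts`
#'   (named list of [transcript_model()]), `variants` (data frame, one row
#'   per modelled site including `ac = 0` rows), `truth_genes`
#'   (`gene_id`, `s_het`), `truth_variants` (`variant_id`,
#'   `is_misannotated`, `origins`, `s_site`), and `config`.
#' @export
simulate_exome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_chrom <- config$n_chrom
  N_e <- config$N_e

  sample_range <- function(range) {
    range[1L] + sample.int(range[2L] - range[1L] + 1L, 1L) - 1L
  }
  txs <- lapply(seq_len(config$n_genes), function(g) {
    simulate_transcript(g, sample_range(config$exons_per_gene))
  })
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  s_gene <- draw_s_het(config$s_het_distribution, config$n_genes)

  per_gene <- lapply(seq_len(config$n_genes), function(g) {
    tx <- txs[[g]]
    n_sites <- sample_range(config$sites_per_gene)
    total <- spliced_length(tx)
    # up to three modelled sites per position (one per alternate allele)
    n_sites <- min(n_sites, 3L * total)
    slot <- sort(sample.int(3L * total, n_sites) - 1L)
    offsets <- slot %/% 3L
    pos <- from_mrna_coord(tx, offsets)  # 0-based genomic
    cons <- sample(names(config$consequence_probs), n_sites, replace = TRUE,
                   prob = config$consequence_probs)
    cls <- sample(names(config$class_probs), n_sites, replace = TRUE,
                  prob = config$class_probs)
    ctx <- class_context(cls)
    jd <- junction_distance(tx, pos)
    csd <- to_mrna_coord(tx, pos)$cds_offset

    mu <- unname(config$mutation_rates[cls])
    is_plof <- cons %in% c("stop_gained", "splice_donor", "splice_acceptor")
    # systematic NMD-escape / start-proximal misannotation of stop-gained;
    # a window of 0 disables the corresponding rule
    escape <- cons == "stop_gained" &
      ((config$nmd_escape_window > 0L & !is.na(jd) &
          jd <= config$nmd_escape_window) |
         csd < config$near_start_window)
    # random misannotation elsewhere among pLoF
    rand_mis <- is_plof & !escape &
      runif(n_sites) < config$misannotation_rate
    mis <- escape | rand_mis

    # latent missense deleteriousness and predictor scores
    u <- runif(n_sites)
    mis_del <- cons == "missense" & u > 0.99
    pred_a <- ifelse(cons == "missense",
                     pmin(1, pmax(0, u + rnorm(n_sites, 0, 0.02))), NA)
    pred_b <- ifelse(cons == "missense",
                     pmin(1, pmax(0, u + rnorm(n_sites, 0, 0.02))), NA)

    is_splice <- cons %in% c("splice_donor", "splice_acceptor")
    splice_score <- rep(NA_real_, n_sites)
    splice_score[is_splice & !mis] <- rbeta(sum(is_splice & !mis), 8, 2)
    splice_score[is_splice & mis] <- rbeta(sum(is_splice & mis), 2, 8)

    s_site <- rep(drift_floor(N_e), n_sites)
    selected <- (is_plof & !mis) | mis_del
    s_site[selected] <- s_gene[g]
    s_eff <- s_effective(s_site, N_e)

    b <- 4 * N_e * s_eff
    lam <- 4 * N_e * mu * log1p(n_chrom / b)
    m_origins <- rpois(n_sites, lam)
    pi_site <- n_chrom / (n_chrom + b)
    ac <- integer(n_sites)
    with_orig <- which(m_origins > 0L)
    for (i in with_orig) {
      ac[i] <- min(sum(rlogarithmic(m_origins[i], pi_site[i])), n_chrom)
    }

    list(
      variants = data.frame(
        variant_id = sprintf("%s_%d_%d", tx$gene_id, pos, slot %% 3L),
        chrom = "chr1",
        pos = pos + 1L,  # external tables are 1-based
        ref = ctx$ref,
        alt = ctx$alt,
        context = ctx$context,
        methylation = ctx$methylation,
        mu = mu,
        consequence = cons,
        ac = ac,
        an = n_chrom,
        gene_id = tx$gene_id,
        transcript_id = tx$transcript_id,
        class = cls,
        pred_a = pred_a,
        pred_b = pred_b,
        splice_score = splice_score,
        stringsAsFactors = FALSE
      ),
      truth = data.frame(
        variant_id = sprintf("%s_%d_%d", tx$gene_id, pos, slot %% 3L),
        gene_id = tx$gene_id,
        is_misannotated = mis,
        origins = m_origins,
        s_site = s_site,
        stringsAsFactors = FALSE
      )
    )
  })

  structure(
    list(
      transcripts = txs,
      variants = do.call(rbind, lapply(per_gene, `[[`, "variants")),
      truth_genes = data.frame(
        gene_id = vapply(txs, `[[`, "", "gene_id"),
        s_het = s_gene,
        stringsAsFactors = FALSE,
        row.names = NULL
      ),
      truth_variants = do.call(rbind, lapply(per_gene, `[[`, "truth")),
      config = config
    ),
    class = "synthetic_exome"
  )
}

#' @export
print.synthetic_exome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_exome> %d genes, %d sites (%d segregating), n_chrom = %g\n",
    length(x$transcripts), nrow(x$variants), sum(x$variants$ac > 0),
    x$config$n_chrom
  ))
  invisible(x)
}

rbetabinom_one <- function(n, size, mean, concentration) {
  p <- rbeta(n, mean * concentration, (1 - mean) * concentration)
  rbinom(n, size, p)
}

#' Simulate allelic-expression read counts
#'
#' Draws per-variant total depths from the configured distribution and
#' alternate-allele read counts from the beta-binomial component each
#' variant is assigned to. The `monoallelic` component is a symmetric
#' two-sided mixture at means `m` and `1 - m`. Zero-depth rows are dropped
#' with a warning.
#'
#' @param components Character vector assigning each simulated variant to
#'   one of `balanced`, `monoallelic`, `random_imbalance`, `nmd`.
#' @param config A [simulation_config()] (supplies depths and component
#'   parameters).
#' @param seed Integer seed; defaults to the config seed.
#' @return Data frame: `variant_id`, `ref_reads`, `alt_reads`, `component`.
#' @export
simulate_ase <- function(components, config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  known <- names(config$ase_components)
  if (!all(components %in% known)) {
    stop("unknown component(s): ",
         paste(setdiff(unique(components), known), collapse = ", "))
  }
  set.seed(seed)
  n <- length(components)
  dd <- config$ase_depth_distribution
  depth <- switch(dd$family,
    nbinom = rnbinom(n, mu = dd$mean, size = dd$size),
    fixed = rep(dd$mean, n),
    stop("unknown depth distribution family: ", dd$family)
  )
  alt <- integer(n)
  for (comp in unique(components)) {
    idx <- which(components == comp)
    par <- config$ase_components[[comp]]
    m <- par$mean
    if (comp == "monoallelic") {
      side <- runif(length(idx)) < 0.5
      alt[idx[side]] <- rbetabinom_one(sum(side), depth[idx[side]],
                                       m, par$concentration)
      alt[idx[!side]] <- rbetabinom_one(sum(!side), depth[idx[!side]],
                                        1 - m, par$concentration)
    } else {
      alt[idx] <- rbetabinom_one(length(idx), depth[idx],
                                 m, par$concentration)
    }
  }
  out <- data.frame(
    variant_id = sprintf("ase%06d", seq_len(n)),
    ref_reads = depth - alt,
    alt_reads = alt,
    component = components,
    stringsAsFactors = FALSE
  )
  if (any(depth == 0L)) {
    warning(sum(depth == 0L), " zero-depth row(s) dropped", call. = FALSE)
    out <- out[depth > 0L, , drop = FALSE]
  }
  out
}

#' Simulate literature-derived gene score tables
#'
#' Literature percentiles are a noisy monotone transform of the true
#' selection strength; a configurable fraction of genes is "understudied"
#' (literature scores forced low regardless of selection), creating genes
#' whose constraint exceeds their literature footprint. The feature-based
#' score sees through the understudied bias (it is driven by selection for
#' all genes), while the literature-derived scores do not. Disease
#' associations are assigned preferentially to well-studied, strongly
#' selected genes.
#'
#' @param exome A [simulate_exome()] result (supplies gene truth).
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to the config seed.
#' @return Data frame: `gene_id`, `pepper_llm_pct`, `pepper_feat_pct`,
#'   `pepper_llm_lof_pct`, `understudied`, `has_disease_assoc`.
#' @export
simulate_gene_scores <- function(exome, config = exome$config,
                                 seed = config$seed) {
  set.seed(seed)
  tg <- exome$truth_genes
  n <- nrow(tg)
  base_pct <- percentile_rank(log(tg$s_het))
  noisy <- function() {
    pmin(100, pmax(0, base_pct + rnorm(n, 0, config$score_noise_sd)))
  }
  understudied <- rep(FALSE, n)
  n_under <- round(config$understudied_fraction * n)
  understudied[sample.int(n, n_under)] <- TRUE

  llm <- noisy()
  llm_lof <- noisy()
  low <- runif(n, 0, 10)
  llm[understudied] <- low[understudied]
  llm_lof[understudied] <- runif(sum(understudied), 0, 10)
  feat <- noisy()  # feature-based: unaffected by study bias

  has_disease <- !understudied & base_pct > 70 & runif(n) < 0.8
  data.frame(
    gene_id = tg$gene_id,
    pepper_llm_pct = llm,
    pepper_feat_pct = feat,
    pepper_llm_lof_pct = llm_lof,
    understudied = understudied,
    has_disease_assoc = has_disease,
    stringsAsFactors = FALSE
  )
}

# percentile rank in (0, 100) with average-rank ties
percentile_rank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}
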
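# Orchestration: runs the module stages in dependency order on a synthetic
# exome, writing TSV artifacts plus a manifest (parameters, per-stage seeds,
# output checksums) that makes a run exactly reproducible. Each stochastic
# stage receives a seed derived from the global seed and the stage name, so
# adding or reordering stages never changes another stage's random stream.

#' Pipeline stages in dependency order
#' @export
PIPELINE_STAGES <- c(
  "simulate", "pneutral", "loftee2", "ase", "constraint", "integrate",
  "evaluate"
)

#' Derive a stage seed from the global seed and stage name
#'
#' Deterministic 31-bit hash of `(seed, stage)`; stable across platforms
#' and R versions.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed in \[0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Run the synthetic-exome analysis pipeline
#'
#' Executes the requested stages in dependency order: simulate the exome
#' (variants, allelic expression, gene scores), fit the neutral spectrum and
#' per-gene mixtures, calibrate and apply the loss-of-function rules, fit
#' the allelic-expression mixture, compute constraint statistics, integrate
#' literature scores, and benchmark. All artifacts are TSV/JSON files under
#' `out_dir`; `manifest.json` records parameters, stage seeds and output
#' checksums. Reruns with the same configuration are byte-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed.
#' @param config Named list of overrides for [simulation_config()]
#'   arguments (`seed` is supplied by the pipeline). Unknown keys are an
#'   error before any stage runs.
#' @param stages Character vector of stages to run (dependencies must have
#'   run into the same `out_dir` previously). Default: all.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, seed, config = list(),
                         stages = PIPELINE_STAGES) {
  known <- setdiff(names(formals(simulation_config)), "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  bad_stage <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(path(f))) {
      stop("stage '", stage, "' needs missing artifact ", f,
           " (run its upstream stage first)")
    }
    path(f)
  }
  cfg <- do.call(simulation_config,
                 c(config, list(seed = stage_seed(seed, "simulate"))))
  manifest <- list(
    seed = seed, stages = list(),
    config = if (length(config)) config[order(names(config))] else list()
  )

  if ("simulate" %in% stages) {
    exome <- simulate_exome(cfg)
    write_variants_tsv(exome$variants, path("variants.tsv"))
    write_transcripts_tsv(exome$transcripts, path("transcripts.tsv"))
    write.table(exome$truth_genes, path("truth_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(exome$truth_variants, path("truth_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # allelic expression: synonymous variants follow the background mix;
    # observed stop-gained variants are NMD when genuine, background when
    # misannotated
    v <- exome$variants
    tv <- exome$truth_variants
    seen <- v$ac >= 1
    syn <- seen & v$consequence == "synonymous"
    stp <- seen & v$consequence == "stop_gained"
    set.seed(stage_seed(seed, "ase_components"))
    bg_draw <- function(n) {
      sample(c("balanced", "monoallelic", "random_imbalance"), n,
             replace = TRUE, prob = c(0.7, 0.1, 0.2))
    }
    comp <- rep(NA_character_, nrow(v))
    comp[syn] <- bg_draw(sum(syn))
    comp[stp] <- ifelse(tv$is_misannotated[stp], bg_draw(sum(stp)), "nmd")
    ase_rows <- which(!is.na(comp))
    ase <- simulate_ase(comp[ase_rows], cfg, seed = stage_seed(seed, "ase_reads"))
    ase$variant_id <- v$variant_id[ase_rows]
    ase$consequence <- v$consequence[ase_rows]
    write.table(ase, path("ase.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    scores <- simulate_gene_scores(exome, cfg,
                                   seed = stage_seed(seed, "gene_scores"))
    write.table(scores, path("gene_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$simulate <- list(seed = cfg$seed,
                                     n_sites = nrow(exome$variants))
  }

  if ("pneutral" %in% stages) {
    v <- read_variants_tsv(need("variants.tsv", "pneutral"))
    neutral <- fit_neutral_sfs(v, n_chrom = cfg$n_chrom)
    fit <- fit_pneutral(v, neutral, n_chrom = cfg$n_chrom, N_e = cfg$N_e)
    write.table(
      fit$variants[, c("variant_id", "gene_id", "ac", "p_neutral",
                       "s_het_mean")],
      path("pneutral.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
    manifest$stages$pneutral <- list(n_variants = nrow(fit$variants))
  }

  if ("loftee2" %in% stages) {
    v <- read_variants_tsv(need("variants.tsv", "loftee2"))
    txs <- read_transcripts_tsv(need("transcripts.tsv", "loftee2"))
    pn <- read.delim(need("pneutral.tsv", "loftee2"))
    plof <- v[v$consequence %in%
                c("stop_gained", "splice_donor", "splice_acceptor") &
                v$ac >= 1, , drop = FALSE]
    feats <- compute_features(plof, txs)
    pmatch_ <- match(feats$variant_id, pn$variant_id)
    # data-driven junction threshold where the cohort supports it; the
    # canonical 50 nt rule otherwise
    cal <- tryCatch(
      calibrate_threshold(
        feats$junction_dist[feats$consequence == "stop_gained"],
        pn$p_neutral[pmatch_][feats$consequence == "stop_gained"],
        seed = stage_seed(seed, "calibrate")
      ),
      error = function(e) list(threshold = NA_real_)
    )
    th <- loftee2_thresholds(
      junction_nt = if (is.na(cal$threshold)) 50 else cal$threshold
    )
    relaxed <- annotate_loftee2(feats, th, mode = "relaxed")
    strict <- annotate_loftee2(feats, th, mode = "strict")
    out <- relaxed
    out$classification_relaxed <- relaxed$classification
    out$classification_strict <- strict$classification
    out$classification <- out$mode <- NULL
    write.table(out, path("loftee2.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$loftee2 <- list(junction_threshold = th$junction_nt)
  }

  if ("ase" %in% stages) {
    ase <- read.delim(need("ase.tsv", "ase"))
    bg <- fit_ase_background(ase[ase$consequence == "synonymous", ])
    nf <- fit_ase_nmd(ase[ase$consequence == "stop_gained", ], bg)
    post <- data.frame(
      variant_id = ase$variant_id[ase$consequence == "stop_gained"],
      p_nmd = nf$posterior[, "nmd"]
    )
    write.table(post, path("ase_posteriors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$ase <- list(weights = as.list(nf$weights))
  }

  if ("constraint" %in% stages) {
    v <- read_variants_tsv(need("variants.tsv", "constraint"))
    counts <- gene_counts_from_exome(v, n_chrom = cfg$n_chrom,
                                     N_e = cfg$N_e)
    write.table(counts, path("gene_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ct <- constraint_table(counts)
    write.table(ct, path("constraint.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$constraint <- list(n_genes = nrow(ct))
  }

  if ("integrate" %in% stages) {
    ct <- read.delim(need("constraint.tsv", "integrate"))
    sc <- read.delim(need("gene_scores.tsv", "integrate"))
    counts <- read.delim(need("gene_counts.tsv", "integrate"))
    m <- merge(merge(ct, sc, by = "gene_id"),
               counts[counts$class == "plof",
                      c("gene_id", "observed", "expected")],
               by = "gene_id")
    m$omelet <- omelet_score(m$pepper_llm_pct, m$observed, m$expected)$omelet
    m$constraint_pct <- percentile_rank(-m$loeuf)
    m$dispo <- dispo_score(m$constraint_pct, m$pepper_llm_lof_pct)
    m$delta_pepper <- delta_pepper(m$pepper_feat_pct, m$pepper_llm_pct)
    write.table(m, path("scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$integrate <- list(
      n_candidates = length(flag_candidates(m))
    )
  }

  if ("evaluate" %in% stages) {
    m <- read.delim(need("scores.tsv", "evaluate"))
    tg <- read.delim(need("truth_genes.tsv", "evaluate"))
    m <- merge(m, tg, by = "gene_id")
    strong <- m$s_het > quantile(m$s_het, 0.8)
    report <- list(
      auprc_omelet = auprc(m$omelet, strong)$auprc,
      auprc_loeuf = auprc(-m$loeuf, strong)$auprc,
      auprc_literature = auprc(m$pepper_llm_pct, strong)$auprc
    )
    jsonlite::write_json(report, path("eval.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$stages$evaluate <- report
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-gene observed and expected counts from a variant table
#'
#' Observed = segregating sites per gene and class; expected = the sum of
#' [prob_segregating()] at the drift floor over the class's modelled sites
#' (the neutral expectation given each site's mutation rate).
#'
#' @param variants Variant data frame including non-segregating rows.
#' @param n_chrom Chromosome sample size.
#' @param N_e Effective population size.
#' @param predictors Missense predictor columns for the top-percentile
#'   class. Default `c("pred_a", "pred_b")` when present.
#' @param pct Top-missense percentage. Default 1.
#' @return Long data frame: `gene_id`, `class` (`plof`, `missense_top`,
#'   `synonymous`), `observed`, `expected`, `possible`.
#' @export
gene_counts_from_exome <- function(variants, n_chrom, N_e = 1e4,
                                   predictors = intersect(
                                     c("pred_a", "pred_b"), names(variants)
                                   ),
                                   pct = 1) {
  v <- variants
  p_neutral_site <- prob_segregating(drift_floor(N_e), v$mu, n_chrom, N_e)
  grp <- rep(NA_character_, nrow(v))
  grp[v$consequence %in%
        c("stop_gained", "splice_donor", "splice_acceptor")] <- "plof"
  grp[v$consequence == "synonymous"] <- "synonymous"
  if (length(predictors)) {
    grp[select_top_percentile(v, predictors, pct)] <- "missense_top"
  }
  keep <- !is.na(grp)
  agg <- aggregate(
    cbind(observed = v$ac[keep] >= 1, expected = p_neutral_site[keep],
          possible = 1L),
    by = list(gene_id = v$gene_id[keep], class = grp[keep]), FUN = sum
  )
  agg[order(agg$gene_id, agg$class), , drop = FALSE]
}
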
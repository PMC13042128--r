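#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnbinom pnbinom dpois rpois rbinom runif rbeta rnorm
#'   rnbinom qgamma pbinom pbeta qbeta quantile median optim setNames
#'   fisher.test aggregate
#' @importFrom utils read.delim write.table head tail
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

MUTATION_CLASSES <- c(
  "methyl_cpg_transition", "unmethyl_cpg_transition",
  "non_cpg_transition", "transversion"
)

#' Default class-level mutation rates
#'
#' Per-site per-generation mutation rates by mutational class, used wherever a
#' per-site rate column is absent. Methylated CpG transitions are roughly an
#' order of magnitude more mutable than other transitions; transversions are
#' the least mutable. The values are round numbers of the magnitude reported
#' for the human germline; per-site rates, when supplied, always override
#' them.
#'
#' @return Named numeric vector of rates, one per mutational class.
#' @export
#' @examples
#' default_mutation_rates()
default_mutation_rates <- function() {
  c(
    methyl_cpg_transition   = 1.2e-07,
    unmethyl_cpg_transition = 1.5e-08,
    non_cpg_transition      = 6.0e-09,
    transversion            = 3.0e-09
  )
}

is_transition <- function(ref, alt) {
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Classify a single-nucleotide change into a mutational class
#'
#' Assigns each (trinucleotide context, alternate allele, methylation) triple
#' to exactly one of four classes: methylated-CpG transition, unmethylated-CpG
#' transition, non-CpG transition, or transversion. A CpG transition is a C>T
#' change with G immediately 3' of the C, or the reverse-strand equivalent
#' G>A with C immediately 5'. Methylation status splits CpG transitions at
#' `methyl_threshold`.
#'
#' @param context Character vector of 3-base reference contexts centred on the
#'   site (middle base is the reference allele).
#' @param alt Character vector of alternate alleles (single bases).
#' @param methylation Numeric vector of mean methylation fractions in
#'   \[0, 1\]; only consulted at CpG sites. `NA` is treated as 0.
#' @param methyl_threshold Methylation fraction at or above which a CpG
#'   transition counts as methylated. Default 0.6.
#' @return Character vector of class labels (see [default_mutation_rates()]
#'   for the label set).
#' @export
#' @examples
#' classify_mutation("ACG", "T", methylation = 0.9)
#' classify_mutation(c("ACA", "AAT"), c("A", "G"), methylation = 0)
classify_mutation <- function(context, alt, methylation = 0,
                              methyl_threshold = 0.6) {
  stopifnot(
    length(methyl_threshold) == 1L,
    methyl_threshold >= 0, methyl_threshold <= 1
  )
  context <- toupper(context)
  alt <- toupper(alt)
  n <- max(length(context), length(alt))
  context <- rep_len(context, n)
  alt <- rep_len(alt, n)
  methylation <- rep_len(ifelse(is.na(methylation), 0, methylation), n)

  if (any(nchar(context) != 3L)) {
    stop("'context' entries must be 3-base strings")
  }
  up <- substr(context, 1L, 1L)
  ref <- substr(context, 2L, 2L)
  down <- substr(context, 3L, 3L)
  if (!all(c(up, ref, down, alt) %in% BASES)) {
    stop("non-ACGT base in context or alt")
  }
  if (any(ref == alt)) stop("alt must differ from the reference base")

  ts <- is_transition(ref, alt)
  # CpG transition on either strand: C>T with 3' G, or G>A with 5' C
  cpg <- (ref == "C" & alt == "T" & down == "G") |
    (ref == "G" & alt == "A" & up == "C")
  out <- rep("transversion", n)
  out[ts] <- "non_cpg_transition"
  out[ts & cpg & methylation >= methyl_threshold] <- "methyl_cpg_transition"
  out[ts & cpg & methylation < methyl_threshold] <- "unmethyl_cpg_transition"
  out
}

#' Construct a transcript model
#'
#' Internal coordinates are 0-based half-open genomic intervals; conversion
#' from 1-based external formats (GTF) happens at the I/O boundary only.
#' Exons must be non-overlapping and are stored sorted in genomic order,
#' whatever the strand. `cds_start`/`cds_end` delimit the coding sequence in
#' genomic coordinates (also 0-based half-open).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   bounds.
#' @param cds_start,cds_end Genomic CDS bounds (0-based half-open), or `NA`
#'   for non-coding models.
#' @return An object of class `transcript_model`. A spliced CDS length that
#'   is absent, zero or not divisible by 3 sets the `valid_cds` flag to
#'   `FALSE` (with a warning) rather than failing.
#' @export
transcript_model <- function(transcript_id, gene_id, strand,
                             exon_starts, exon_ends,
                             cds_start = NA, cds_end = NA) {
  stopifnot(
    strand %in% c("+", "-"),
    length(exon_starts) == length(exon_ends),
    length(exon_starts) >= 1L,
    all(exon_ends > exon_starts)
  )
  ord <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[ord])
  exon_ends <- as.integer(exon_ends[ord])
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
    stop("exons overlap")
  }
  tx <- structure(
    list(
      transcript_id = as.character(transcript_id),
      gene_id = as.character(gene_id),
      strand = strand,
      exon_starts = exon_starts,
      exon_ends = exon_ends,
      cds_start = if (is.na(cds_start)) NA_integer_ else as.integer(cds_start),
      cds_end = if (is.na(cds_end)) NA_integer_ else as.integer(cds_end),
      valid_cds = FALSE
    ),
    class = "transcript_model"
  )
  if (!is.na(cds_start) && !is.na(cds_end) && cds_end > cds_start) {
    len <- spliced_cds_length(tx)
    tx$valid_cds <- len > 0L && len %% 3L == 0L
    if (!tx$valid_cds) {
      warning(sprintf(
        "transcript %s: spliced CDS length %d not a positive multiple of 3",
        transcript_id, len
      ), call. = FALSE)
    }
  }
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s) strand %s, %d exon(s), spliced length %d\n",
    x$transcript_id, x$gene_id, x$strand,
    length(x$exon_starts), sum(x$exon_ends - x$exon_starts)
  ))
  invisible(x)
}

exon_lengths <- function(tx) tx$exon_ends - tx$exon_starts

spliced_length <- function(tx) sum(exon_lengths(tx))

spliced_cds_length <- function(tx) {
  if (is.na(tx$cds_start) || is.na(tx$cds_end)) return(0L)
  sum(pmax(0L, pmin(tx$exon_ends, tx$cds_end) -
             pmax(tx$exon_starts, tx$cds_start)))
}

#' Map genomic positions onto spliced-transcript coordinates
#'
#' Returns 0-based offsets along the mature (spliced) transcript, oriented
#' 5' to 3' on the coding strand, together with the CDS-relative offset where
#' the position is coding. Positions are 0-based, the same convention as the
#' exon bounds (1-based external formats are converted at the I/O boundary).
#' Intronic positions yield `NA` offsets (an explicit "not exonic" result),
#' not an error, so splice-site variants can flow through annotation.
#'
#' @param tx A [transcript_model()].
#' @param genomic_pos Integer vector of 0-based genomic positions.
#' @return Data frame with columns `genomic_pos`, `exonic` (logical),
#'   `mrna_offset` and `cds_offset` (0-based; `NA` when not applicable).
#' @export
to_mrna_coord <- function(tx, genomic_pos) {
  stopifnot(inherits(tx, "transcript_model"))
  pos0 <- as.integer(genomic_pos)
  n_ex <- length(tx$exon_starts)
  cum <- c(0L, cumsum(exon_lengths(tx)))  # plus-strand cumulative offsets
  total <- spliced_length(tx)

  offset_plus <- rep(NA_integer_, length(pos0))
  for (i in seq_len(n_ex)) {
    inside <- pos0 >= tx$exon_starts[i] & pos0 < tx$exon_ends[i]
    offset_plus[inside] <- cum[i] + (pos0[inside] - tx$exon_starts[i])
  }
  mrna <- if (tx$strand == "+") offset_plus else total - 1L - offset_plus

  cds_off <- rep(NA_integer_, length(pos0))
  if (!is.na(tx$cds_start) && !is.na(tx$cds_end)) {
    cs <- cds_mrna_bounds(tx)
    coding <- !is.na(mrna) & mrna >= cs[1L] & mrna <= cs[2L]
    cds_off[coding] <- mrna[coding] - cs[1L]
  }
  data.frame(
    genomic_pos = as.integer(genomic_pos),
    exonic = !is.na(mrna),
    mrna_offset = mrna,
    cds_offset = cds_off
  )
}

# mRNA offsets (0-based, inclusive) of the first and last coding base
cds_mrna_bounds <- function(tx) {
  m1 <- to_mrna_raw(tx, tx$cds_start)       # leftmost CDS base
  m2 <- to_mrna_raw(tx, tx$cds_end - 1L)    # rightmost CDS base
  sort(c(m1, m2))
}

to_mrna_raw <- function(tx, genomic_pos) {
  pos0 <- genomic_pos
  cum <- c(0L, cumsum(exon_lengths(tx)))
  off <- NA_integer_
  for (i in seq_along(tx$exon_starts)) {
    if (pos0 >= tx$exon_starts[i] && pos0 < tx$exon_ends[i]) {
      off <- cum[i] + (pos0 - tx$exon_starts[i])
    }
  }
  if (tx$strand == "+") off else spliced_length(tx) - 1L - off
}

#' Inverse coordinate mapping: spliced offset back to genomic position
#'
#' @param tx A [transcript_model()].
#' @param mrna_offset 0-based offsets along the mature transcript.
#' @return Integer vector of 0-based genomic positions.
#' @export
from_mrna_coord <- function(tx, mrna_offset) {
  stopifnot(inherits(tx, "transcript_model"))
  total <- spliced_length(tx)
  stopifnot(all(mrna_offset >= 0L & mrna_offset < total))
  off_plus <- if (tx$strand == "+") mrna_offset else total - 1L - mrna_offset
  cum <- c(0L, cumsum(exon_lengths(tx)))
  idx <- findInterval(off_plus, cum, rightmost.closed = FALSE)
  tx$exon_starts[idx] + (off_plus - cum[idx])
}

#' Signed distance to the last exon-exon junction
#'
#' In spliced-transcript coordinates, the final junction sits at the first
#' base of the last (most 3') exon. The returned distance is
#' `junction offset - variant offset`: positive when the variant lies
#' upstream of the final junction (where a premature termination codon can
#' trigger nonsense-mediated decay) and zero or negative inside the last
#' exon. Single-exon transcripts have no junction and yield `NA`.
#'
#' @param tx A [transcript_model()].
#' @param genomic_pos 0-based genomic positions (must be exonic).
#' @return Integer vector of signed distances (`NA` for single-exon models or
#'   non-exonic positions).
#' @export
#' @examples
#' tx <- transcript_model("t", "g", "+", c(0, 200), c(100, 250),
#'                        cds_start = 0, cds_end = 249)
#' junction_distance(tx, 96)  # 5 nt upstream of the final junction
junction_distance <- function(tx, genomic_pos) {
  stopifnot(inherits(tx, "transcript_model"))
  if (length(tx$exon_starts) < 2L) {
    return(rep(NA_integer_, length(genomic_pos)))
  }
  # first base of the genomically-last exon on +, genomically-first on -
  junc_g <- if (tx$strand == "+") {
    tx$exon_starts[length(tx$exon_starts)]
  } else {
    tx$exon_ends[1L] - 1L
  }
  junc_off <- to_mrna_raw(tx, junc_g)
  m <- to_mrna_coord(tx, genomic_pos)
  as.integer(junc_off) - m$mrna_offset
}

#' Distance from the CDS start
#'
#' Strand-aware distance, in spliced coding coordinates, from the first
#' coding base (0 at the first base of the start codon).
#'
#' @param tx A [transcript_model()].
#' @param genomic_pos 0-based genomic positions within the CDS.
#' @return Non-negative integer vector.
#' @export
cds_start_distance <- function(tx, genomic_pos) {
  m <- to_mrna_coord(tx, genomic_pos)
  if (any(is.na(m$cds_offset))) {
    stop("position(s) outside the coding sequence: ",
         paste(genomic_pos[is.na(m$cds_offset)], collapse = ", "))
  }
  m$cds_offset
}

#' Distance to the transcript 3' end
#'
#' Nucleotides from the variant to the last base of the mature transcript
#' (0 at the final base). Used by the single-exon rules, where junction-based
#' NMD logic does not apply.
#'
#' @param tx A [transcript_model()].
#' @param genomic_pos 0-based genomic positions (exonic).
#' @return Non-negative integer vector (`NA` for non-exonic positions).
#' @export
transcript_end_distance <- function(tx, genomic_pos) {
  m <- to_mrna_coord(tx, genomic_pos)
  spliced_length(tx) - 1L - m$mrna_offset
}

# ---- I/O ------------------------------------------------------------------

VARIANT_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "context", "methylation", "mu",
  "consequence", "ac", "an"
)

CONSEQUENCES <- c(
  "synonymous", "missense", "stop_gained", "splice_donor", "splice_acceptor"
)

validate_variants <- function(df, file = "<data>") {
  missing_cols <- setdiff(
    c("chrom", "pos", "ref", "alt", "consequence", "ac", "an"), names(df)
  )
  if (length(missing_cols)) {
    stop(sprintf("%s: missing mandatory column(s): %s",
                 file, paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(VARIANT_COLUMNS, names(df))) df[[col]] <- NA
  bad <- which(!(df$ac >= 0 & df$ac <= df$an & df$an > 0))
  if (length(bad)) {
    stop(sprintf("%s: invalid AC/AN on row(s) %s",
                 file, paste(head(bad, 5L), collapse = ", ")))
  }
  bad_cons <- which(!df$consequence %in% CONSEQUENCES)
  if (length(bad_cons)) {
    stop(sprintf("%s: unknown consequence on row(s) %s",
                 file, paste(head(bad_cons, 5L), collapse = ", ")))
  }
  ctx_ok <- is.na(df$context) | nchar(df$context) == 3L
  if (!all(ctx_ok)) {
    stop(sprintf("%s: malformed context on row(s) %s",
                 file, paste(head(which(!ctx_ok), 5L), collapse = ", ")))
  }
  mid <- substr(df$context, 2L, 2L)
  ref_ok <- is.na(df$context) | mid == df$ref
  if (!all(ref_ok)) {
    stop(sprintf("%s: context middle base != ref on row(s) %s",
                 file, paste(head(which(!ref_ok), 5L), collapse = ", ")))
  }
  df
}

#' Read a variant table from TSV
#'
#' Expected columns: `chrom, pos, ref, alt, context, methylation, mu,
#' consequence, ac, an`, plus any number of optional per-predictor score
#' columns (e.g. `splice_score`, missense predictor columns). `pos` is
#' 1-based. Malformed rows are reported with their row numbers.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return Data frame of variants, one row per site.
#' @export
read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_variants(df, file = path)
}

#' Write a variant table to TSV
#'
#' @param variants Data frame as returned by [read_variants_tsv()] or
#'   [simulate_exome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variants from a minimal VCF dialect
#'
#' Parses a sites-only VCF via \pkg{vcfR}. Mandatory INFO keys: `AC`, `AN`;
#' optional keys: `MU` (per-site mutation rate), `METHYL` (methylation
#' fraction), `SPLICE_SCORE`, `CSQ` (one consequence term from the package's
#' vocabulary) and `CONTEXT` (trinucleotide).
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @return Data frame in the same layout as [read_variants_tsv()].
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  ac <- info_num("AC")
  an <- info_num("AN")
  if (all(is.na(ac))) stop(path, ": missing mandatory INFO key AC")
  if (all(is.na(an))) stop(path, ": missing mandatory INFO key AN")
  df <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    context = vcfR::extract.info(v, element = "CONTEXT"),
    methylation = info_num("METHYL"),
    mu = info_num("MU"),
    consequence = vcfR::extract.info(v, element = "CSQ"),
    ac = as.integer(ac),
    an = as.integer(an),
    stringsAsFactors = FALSE
  )
  ss <- info_num("SPLICE_SCORE")
  if (!all(is.na(ss))) df$splice_score <- ss
  validate_variants(df, file = path)
}

#' Read transcript models from a TSV
#'
#' Columns: `transcript_id, gene_id, strand, exon_starts, exon_ends,
#' cds_start, cds_end`; `exon_starts`/`exon_ends` are comma-separated lists
#' of 0-based half-open bounds.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "strand", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  split_ints <- function(s) as.integer(strsplit(s, ",")[[1L]])
  out <- lapply(seq_len(nrow(df)), function(i) {
    transcript_model(
      df$transcript_id[i], df$gene_id[i], df$strand[i],
      split_ints(df$exon_starts[i]), split_ints(df$exon_ends[i]),
      cds_start = if ("cds_start" %in% names(df)) df$cds_start[i] else NA,
      cds_end = if ("cds_end" %in% names(df)) df$cds_end[i] else NA
    )
  })
  names(out) <- df$transcript_id
  out
}

#' Write transcript models to TSV
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  df <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(
      transcript_id = tx$transcript_id,
      gene_id = tx$gene_id,
      strand = tx$strand,
      exon_starts = paste(tx$exon_starts, collapse = ","),
      exon_ends = paste(tx$exon_ends, collapse = ","),
      cds_start = tx$cds_start,
      cds_end = tx$cds_end,
      stringsAsFactors = FALSE
    )
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Imports `exon` and `CDS` features with \pkg{rtracklayer} and assembles one
#' [transcript_model()] per `transcript_id`. GTF 1-based closed intervals are
#' converted to the package's 0-based half-open convention at this boundary.
#'
#' @param path Path to a GTF file.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  exons <- md[md$type == "exon", , drop = FALSE]
  cds <- md[md$type == "CDS", , drop = FALSE]
  if (!nrow(exons)) stop(path, ": no exon features found")
  out <- lapply(split(exons, exons$transcript_id), function(e) {
    tid <- e$transcript_id[1L]
    cc <- cds[cds$transcript_id == tid, , drop = FALSE]
    transcript_model(
      tid,
      gene_id = e$gene_id[1L],
      strand = as.character(e$strand[1L]),
      exon_starts = e$start - 1L, exon_ends = e$end,
      cds_start = if (nrow(cc)) min(cc$start) - 1L else NA,
      cds_end = if (nrow(cc)) max(cc$end) else NA
    )
  })
  out[order(names(out))]
}
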
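test_that("mutation classification matches its definitions", {
  expect_equal(classify_mutation("ACG", "T", methylation = 0.9),
               "methyl_cpg_transition")
  expect_equal(classify_mutation("ACG", "T", methylation = 0.1),
               "unmethyl_cpg_transition")
  # reverse-strand CpG: G>A with 5' C
  expect_equal(classify_mutation("CGT", "A", methylation = 0.8),
               "methyl_cpg_transition")
  expect_equal(classify_mutation("ACA", "A", methylation = 0),
               "transversion")
  expect_equal(classify_mutation("AAT", "G", methylation = 0),
               "non_cpg_transition")
  expect_error(classify_mutation("ANG", "T"), "non-ACGT")
  expect_error(classify_mutation("ACG", "C"), "differ")
})

test_that("classification partitions all 192 context-alt combinations", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(up = bases, ref = bases, down = bases, alt = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  expect_equal(nrow(combos), 192L)
  for (meth in c(0, 1)) {
    cls <- classify_mutation(
      paste0(combos$up, combos$ref, combos$down), combos$alt,
      methylation = meth
    )
    expect_true(all(cls %in% c(
      "methyl_cpg_transition", "unmethyl_cpg_transition",
      "non_cpg_transition", "transversion"
    )))
    # transitions and transversions split 1:2
    expect_equal(sum(cls == "transversion"), 128L)
  }
})

test_that("mRNA coordinates follow strand and splicing", {
  plus <- transcript_model("t1", "g1", "+", 100, 200)
  expect_equal(to_mrna_coord(plus, 101)$mrna_offset, 1L)
  minus <- transcript_model("t2", "g2", "-", 100, 200)
  expect_equal(to_mrna_coord(minus, 199)$mrna_offset, 0L)
  two <- transcript_model("t3", "g3", "+", c(0, 20), c(10, 30))
  expect_equal(to_mrna_coord(two, 21)$mrna_offset, 11L)
  # intronic: explicit not-exonic result, no error
  res <- to_mrna_coord(two, 15)
  expect_false(res$exonic)
  expect_true(is.na(res$mrna_offset))
})

test_that("genomic -> mRNA -> genomic is the identity on random transcripts", {
  set.seed(11)
  for (rep in 1:25) {
    tx <- suppressWarnings(random_transcript())
    oracle <- splice_oracle(tx)
    pos <- sample(oracle, min(20L, length(oracle)))
    m <- to_mrna_coord(tx, pos)
    expect_true(all(m$exonic))
    expect_equal(from_mrna_coord(tx, m$mrna_offset), pos)
    # offsets agree with the base-by-base oracle
    expect_equal(m$mrna_offset, match(pos, oracle) - 1L)
  }
})

test_that("junction and CDS-start distances match a brute-force oracle", {
  tx <- transcript_model("t", "g", "+", c(0, 200), c(100, 250),
                         cds_start = 0, cds_end = 250)
  expect_equal(junction_distance(tx, 95), 5L)
  expect_equal(junction_distance(tx, 200), 0L)  # first base of last exon
  expect_equal(junction_distance(tx, 210), -10L)  # inside the last exon
  single <- transcript_model("s", "g", "+", 0, 99)
  expect_true(is.na(junction_distance(single, 10)))

  # minus strand: the genomically-last CDS base is the first coding base
  mtx <- transcript_model("m", "g", "-", 100, 220,
                          cds_start = 100, cds_end = 220)
  expect_equal(cds_start_distance(mtx, 219), 0L)
  expect_equal(cds_start_distance(mtx, 200), 19L)
  ptx <- transcript_model("p", "g", "+", 100, 220,
                          cds_start = 100, cds_end = 220)
  expect_equal(cds_start_distance(ptx, 100), 0L)
  expect_equal(cds_start_distance(ptx, 130), 30L)
  expect_error(cds_start_distance(ptx, 50), "outside the coding")

  set.seed(42)
  for (rep in 1:25) {
    tx <- suppressWarnings(random_transcript())
    if (length(tx$exon_starts) < 2L) next
    oracle <- splice_oracle(tx)
    # oracle junction offset: index (0-based) of the first base of the
    # final exon in transcription order
    last_exon_first_base <- if (tx$strand == "+") {
      tx$exon_starts[length(tx$exon_starts)]
    } else {
      tx$exon_ends[1L] - 1L
    }
    junc <- match(last_exon_first_base, oracle) - 1L
    pos <- sample(oracle, 15L, replace = TRUE)
    expect_equal(junction_distance(tx, pos),
                 junc - (match(pos, oracle) - 1L))
    expect_equal(cds_start_distance(tx, pos), match(pos, oracle) - 1L)
  }
})

test_that("variant tables round-trip through TSV and the VCF dialect", {
  v <- data.frame(
    chrom = "chr1", pos = c(101L, 205L), ref = c("C", "A"),
    alt = c("T", "C"), context = c("ACG", "AAT"),
    methylation = c(0.9, 0), mu = c(1.2e-7, 6e-9),
    consequence = c("synonymous", "stop_gained"),
    ac = c(5L, 1L), an = c(1000L, 1000L),
    stringsAsFactors = FALSE
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(v, tsv)
  expect_equal(read_variants_tsv(tsv), v)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t101\t.\tC\tT\t.\t.\t",
           "AC=5;AN=1000;MU=1.2e-07;METHYL=0.9;CSQ=synonymous;CONTEXT=ACG")
  ), vcf)
  vv <- read_variants_vcf(vcf)
  expect_equal(vv$ac, 5L)
  expect_equal(vv$an, 1000L)
  expect_equal(vv$mu, 1.2e-7)
  expect_equal(vv$consequence, "synonymous")
  expect_equal(vv$context, "ACG")

  # missing mandatory column is named
  bad <- v
  bad$ac <- NULL
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variants_tsv(tsv2), "ac")
})

test_that("transcripts round-trip through TSV and import from GTF", {
  tx <- transcript_model("tx1", "g1", "+", c(0, 200), c(100, 250),
                         cds_start = 10, cds_end = 230)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts_tsv(list(tx1 = tx), tsv)
  back <- read_transcripts_tsv(tsv)[["tx1"]]
  expect_equal(back$exon_starts, tx$exon_starts)
  expect_equal(back$cds_end, tx$cds_end)
  expect_equal(back$strand, "+")

  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr_str <- 'gene_id "g1"; transcript_id "tx1";'
  writeLines(c(
    paste("chr1", "test", "exon", 1, 100, ".", "+", ".", attr_str,
          sep = "\t"),
    paste("chr1", "test", "exon", 201, 250, ".", "+", ".", attr_str,
          sep = "\t"),
    paste("chr1", "test", "CDS", 11, 230, ".", "+", ".", attr_str,
          sep = "\t")
  ), gtf)
  gg <- read_transcripts_gtf(gtf)[["tx1"]]
  expect_equal(gg$exon_starts, c(0L, 200L))
  expect_equal(gg$exon_ends, c(100L, 250L))
  expect_equal(gg$cds_start, 10L)
  expect_equal(gg$cds_end, 230L)
})

test_that("invalid transcript CDS flags a warning, not an error", {
  expect_warning(
    tx <- transcript_model("t", "g", "+", 0, 100, cds_start = 0,
                           cds_end = 98),
    "multiple of 3"
  )
  expect_false(tx$valid_cds)
})
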
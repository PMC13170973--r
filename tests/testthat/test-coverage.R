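alnDf <- function(read_id, taxon_id, pos, cigar, flag = 0L) {
  n <- length(read_id)
  data.frame(read_id = read_id, flag = rep_len(flag, n),
             taxon_id = taxon_id, pos = pos, mapq = rep_len(60L, n),
             cigar = cigar, read_length = rep_len(NA_integer_, n),
             stringsAsFactors = FALSE)
}

test_that("single and overlapping alignments give the expected depths", {
  one <- alnDf("r1", "t", 1L, "10M")
  d <- depthProfile(one, 20L)
  expect_identical(as.integer(d), c(rep(1L, 10), rep(0L, 10)))

  two <- alnDf(c("r1", "r2"), "t", c(1L, 6L), c("10M", "10M"))
  d2 <- as.integer(depthProfile(two, 20L))
  expect_identical(d2[6:10], rep(2L, 5))
  expect_identical(d2[1:5], rep(1L, 5))
  expect_identical(d2[11:15], rep(1L, 5))
  expect_identical(max(d2), 2L)
})

test_that("deletions are spanned but not covered", {
  d <- as.integer(depthProfile(alnDf("r1", "t", 1L, "5M4D5M"), 20L))
  expect_identical(d, c(rep(1L, 5), rep(0L, 4), rep(1L, 5), rep(0L, 6)))
})

test_that("an alignment overrunning the reference names the read", {
  expect_error(depthProfile(alnDf("runaway", "t", 95L, "10M"), 100L),
               "runaway")
})

test_that("depth profile equals per-base brute-force accumulation exactly", {
  set.seed(17)
  width <- 500L
  n <- 200L
  pos <- sample.int(400L, n, replace = TRUE)
  cig <- vapply(seq_len(n), function(i) randomCigar(sample(10:60, 1)),
                character(1))
  aln <- alnDf(sprintf("x%03d", seq_len(n)), "t", pos, cig)

  oracle <- integer(width)
  for (i in seq_len(n)) {
    oracle <- oracle + oracleRefCover(cig[i], pos[i], width)
  }
  expect_identical(as.integer(depthProfile(aln, width)), oracle)
  # conservation: total depth mass equals the summed aligned spans
  expect_identical(sum(oracle), sum(alignedRefSpan(cig)))
})

test_that("taxon summary reproduces printed worked-example arithmetic", {
  # mean depth from mapped-base total and genome length
  expect_equal(signif(30146240 / 6792330, 2), 4.4)
  d <- depthProfile(alnDf("r", "t", 1L, "100M"), 200L)
  ts <- taxonSummary(d, readLengths = 150, "t", 200L)
  expect_equal(ts$taxon_mean_coverage, 0.5)
  expect_equal(ts$taxon_covered_bases_X, 100)
  expect_equal(ts$taxon_pct_covered_bases_X, 50)
  expect_equal(ts$total_taxon_ref_mapped_bases, 100)
  expect_equal(ts$taxon_mean_read_length, 150)
})

test_that("covered bases are non-increasing in the threshold", {
  set.seed(19)
  n <- 60L
  aln <- alnDf(sprintf("m%02d", 1:n), "t",
               sample.int(300L, n, replace = TRUE),
               paste0(sample(20:80, n, replace = TRUE), "M"))
  d <- depthProfile(aln, 400L)
  cov <- vapply(1:6, function(X)
    taxonSummary(d, 100, "t", 400L, threshold = X)$taxon_covered_bases_X,
    numeric(1))
  expect_true(all(diff(cov) <= 0))
})

test_that("zero alignments produce an all-zero taxon row", {
  ref <- Biostrings::DNAStringSet(c(tA = strrep("ACGT", 100)))
  stats <- computeTaxonStats(alnDf(character(0), character(0), integer(0),
                                   character(0)),
                             randomReadSet(3, len = 20), ref)
  expect_identical(nrow(stats), 2L)             # taxon row + "*" row
  expect_identical(stats$taxon_id, c("tA", "*"))
  expect_true(all(stats$taxon_mean_coverage == 0))
  expect_true(all(stats$taxon_pct_covered_bases_X == 0))
})

test_that("manifest rows join FASTQ, QC, alignment and summary fields", {
  reads <- randomReadSet(4, len = 40)           # r001..r004
  status <- setNames(c(TRUE, TRUE, FALSE, TRUE), names(reads))
  aln <- alnDf(c("r001", "r002"), c("tA", "tB"), c(1L, 1L), c("40M", "40M"))
  summ <- data.frame(
    read_id = c("r001", "r002", "r002", "r003"),
    channel = c(232L, 88L, 88L, 211L),
    start_time = c(48.34, 50.16, 61.0, 108.37),
    duration = c(2.28, 1.17, 1.0, 3.18),
    sequence_length_template = c(825, 272, 272, 1342),
    mean_qscore_template = c(14.04, 11.29, 11.29, 9.13),
    end_reason = c("Signal_positive", "signal_positive",
                   "signal_negative", "signal_positive"),
    stringsAsFactors = FALSE)
  m <- buildManifest(reads, status, aln, summ, sampleId = "Test")

  expect_identical(nrow(m), 5L)                 # r002 twice, r004 no row
  expect_true(all(m$read_id %in% names(reads)))
  expect_setequal(unique(m$read_id), names(reads))   # completeness

  r1 <- m[m$read_id == "r001", ]
  expect_true(r1$fastp_status && r1$is_mapped && r1$is_uniq)
  expect_identical(r1$contig_id, "tA")
  expect_equal(r1$end_time, 48.34 + 2.28)

  r2 <- m[m$read_id == "r002", ]
  expect_identical(nrow(r2), 2L)
  expect_false(any(r2$is_uniq))                 # re-evaluated strand

  r3 <- m[m$read_id == "r003", ]                # qc-fail: never mapped
  expect_false(r3$fastp_status || r3$is_mapped)
  expect_identical(r3$contig_id, "")

  r4 <- m[m$read_id == "r004", ]                # no summary row
  expect_true(is.na(r4$channel))
  expect_equal(r4$read_qscore, meanQscore(reads["r004"]), tolerance = 1e-9)
})

test_that("without a summary, Q scores come from the FASTQ qualities", {
  reads <- randomReadSet(3, len = 30, q = 17)
  status <- setNames(rep(TRUE, 3), names(reads))
  m <- buildManifest(reads, status,
                     alnDf(character(0), character(0), integer(0),
                           character(0)))
  expect_identical(nrow(m), 3L)
  expect_equal(m$read_qscore, rep(17, 3), tolerance = 1e-9)
  expect_true(all(m$is_uniq))
  expect_true(all(m$decision == ""))
})

test_that("manifest summary orders taxa with the unmapped row last", {
  ref <- Biostrings::DNAStringSet(c(zeta = strrep("A", 50),
                                    alpha = strrep("C", 50)))
  aln <- alnDf(c("r001", "r002"), c("zeta", "alpha"), c(1L, 1L),
               c("20M", "30M"))
  reads <- randomReadSet(2, len = 40)
  stats <- computeTaxonStats(aln, reads, ref)
  qc <- qcFilter(reads)$stats
  ms <- buildManifestSummary(stats, qc,
                             list(genome_size = 1234, coverage = 5.6))
  expect_identical(ms$taxon_id, c("alpha", "zeta", "*"))
  expect_identical(ms$est_genome_size, rep(1234, 3))
  expect_identical(ms$total_bases, rep(qc$total_bases, 3))
  # conservation across taxa
  expect_equal(sum(ms$total_taxon_ref_mapped_bases),
               sum(alignedRefSpan(aln$cigar)))
  # mean coverage times length recovers the mapped-base total
  body <- ms[ms$taxon_id != "*", ]
  expect_equal(body$taxon_mean_coverage * body$taxon_length,
               body$total_taxon_ref_mapped_bases)
})

test_that("summary files carry the active threshold in their column names", {
  ref <- Biostrings::DNAStringSet(c(tA = strrep("ACGT", 25)))
  reads <- randomReadSet(1, len = 20)
  stats <- computeTaxonStats(alnDf("r001", "tA", 1L, "20M"), reads, ref,
                             threshold = 5)
  ms <- buildManifestSummary(stats, qcFilter(reads)$stats)
  f <- tempfile()
  writeManifestSummary(ms, f, threshold = 5)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_true("taxon_%_covered_bases_5X" %in% hdr)
  expect_true("taxon_covered_bases_5X" %in% hdr)
  back <- readManifestSummary(f)
  expect_identical(attr(back, "threshold"), 5)
  expect_equal(back$taxon_mean_coverage, ms$taxon_mean_coverage,
               tolerance = 1e-12)
})
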
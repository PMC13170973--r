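# fixtures are built in code at test time; nothing binary ships with the
# package

writeTempFastq <- function(lines) {
  f <- tempfile(fileext = ".fastq")
  writeLines(lines, f)
  f
}

# n random reads as an in-memory set (uniform sequences, constant q)
randomReadSet <- function(n, len = 50, q = 20, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%03d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  quals <- strrep(rawToChar(as.raw(q + 33L)), len)
  newFastqSet(ids, seqs, quals)
}

# synthetic sequencing summary covering all 512 channels
syntheticSummary <- function(n = 512, seed = 1) {
  set.seed(seed)
  data.frame(
    read_id = sprintf("s%04d", seq_len(n)),
    channel = rep_len(seq_len(512), n),
    start_time = runif(n, 0, 7200),
    duration = runif(n, 0.5, 20),
    sequence_length_template = sample(200:5000, n, replace = TRUE),
    mean_qscore_template = runif(n, 5, 20),
    end_reason = sample(c("signal_positive", "data_service_unblock_mux_change",
                          "signal_negative", "unblock_mux_change"),
                        n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# hand-rolled SAM text writer for small fixtures
writeTempSam <- function(sq, records) {
  f <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  writeLines(c(hdr, records), f)
  f
}

samLine <- function(qname, flag, rname, pos, cigar, mapq = 60,
                    seq = "*", qual = "*") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, mapq, cigar, seq, qual)
}

# independent per-base oracle for reference bases covered by a CIGAR:
# walk the operations, advancing/depositing per SAM semantics
oracleRefCover <- function(cigar, pos, width) {
  depth <- integer(width)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  at <- pos
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X")) {
      depth[at:(at + lens[i] - 1L)] <- depth[at:(at + lens[i] - 1L)] + 1L
      at <- at + lens[i]
    } else if (ops[i] %in% c("D", "N")) {
      at <- at + lens[i]
    } # I/S/H/P consume no reference
  }
  depth
}

randomCigar <- function(readLen) {
  # random alternation of M with occasional I/D/S, consuming readLen query
  parts <- character(0)
  left <- readLen
  if (runif(1) < 0.3) {
    s <- sample.int(min(10L, left - 1L), 1L)
    parts <- c(parts, paste0(s, "S")); left <- left - s
  }
  while (left > 0) {
    m <- sample.int(left, 1L)
    parts <- c(parts, paste0(m, "M")); left <- left - m
    if (left > 0 && runif(1) < 0.5) {
      if (runif(1) < 0.5) {
        i <- sample.int(left, 1L)
        parts <- c(parts, paste0(i, "I")); left <- left - i
      } else {
        parts <- c(parts, paste0(sample.int(8L, 1L), "D"))
      }
    }
  }
  paste(parts, collapse = "")
}

# a small but complete synthetic AS run shared by the heavier test files,
# analyzed once per condition through the truth-SAM path; built lazily
.fixtures <- new.env(parent = emptyenv())

smallScenario <- function(seed = 104) {
  runScenario(
    taxa = data.frame(
      taxon_id = c("Mock_target", "Mock_commensal_A",
                   "Mock_commensal_B", "Mock_rare"),
      genome_length = c(12000L, 8000L, 6000L, 4000L),
      abundance = c(0.80, 0.10, 0.06, 0.04)),
    readCount = 1200, readLengthMeanlog = log(800), readLengthSdlog = 0.6,
    errorRate = 0.02, runDuration = 3600, seed = seed)
}

smallRunFixture <- function() {
  if (!is.null(.fixtures$run)) return(.fixtures$run)
  dir <- file.path(tempdir(), "poreSight-small-run")
  run <- generateRun(smallScenario(), file.path(dir, "sim"))
  summ <- readSequencingSummary(run$summary)
  reads <- readFastq(run$fastq)
  ft <- filterONT(summ, reads, file.path(dir, "test"),
                  filterCriteria(min_ch = 1, max_ch = 256))
  fc <- filterONT(summ, reads, file.path(dir, "control"),
                  filterCriteria(min_ch = 257, max_ch = 512))
  at <- runAnalyze(ft$fastq, run$reference, file.path(dir, "test_out"),
                   summary = run$summary, sam = run$sam, sampleId = "test")
  ac <- runAnalyze(fc$fastq, run$reference, file.path(dir, "control_out"),
                   summary = run$summary, sam = run$sam, sampleId = "control")
  .fixtures$run <- list(dir = dir, run = run, summary = summ, reads = reads,
                        test = at, control = ac)
  .fixtures$run
}
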
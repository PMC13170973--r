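randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# independent oracle: canonical k-mers by per-window string reverse
# complement, coded differently from the package implementation
oracleCanonical <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in 1:(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", km)) next
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", km), "")[[1]]),
                collapse = "")
    out <- c(out, if (km <= rc) km else rc)
  }
  out
}

test_that("canonical k-mers handle palindromes and strand choice", {
  expect_identical(canonicalKmers("ACGT", 4), "ACGT")   # self-revcomp
  expect_identical(canonicalKmers("AAAA", 4), "AAAA")   # revcomp TTTT larger
  expect_identical(canonicalKmers("TTTT", 4), "AAAA")   # maps to the minus strand
  expect_identical(canonicalKmers("ACG", 4), character(0))
  expect_identical(canonicalKmers("ACNGT", 2), c("AC", "AC"))  # N windows skipped
})

test_that("canonical k-mers equal a brute-force double-strand scan", {
  set.seed(31)
  for (k in c(3, 11, 27)) {
    s <- randomSeq(300)
    expect_identical(canonicalKmers(s, k), oracleCanonical(s, k))
  }
})

test_that("the sketch is deterministic and read-order invariant", {
  set.seed(33)
  seqs <- vapply(1:50, function(i) randomSeq(500), character(1))
  seqs <- c(seqs, seqs[1:10])                      # repeats so m=2 retains
  s1 <- sketchReads(seqs, k = 15, s = 200, m = 2)
  s2 <- sketchReads(sample(seqs), k = 15, s = 200, m = 2)
  expect_identical(s1@hashes, s2@hashes)
  expect_identical(s1@multiplicities, s2@multiplicities)
  s3 <- sketchReads(seqs, k = 15, s = 200, m = 2, seed = 99)
  expect_false(identical(s1@hashes, s3@hashes))    # seed changes the hash
})

test_that("a read repeated 10x retains all its k-mers at multiplicity 10", {
  set.seed(35)
  r <- randomSeq(200)
  sk <- sketchReads(rep(r, 10), k = 27, s = 1000, m = 2)
  expect_identical(length(sk@hashes),
                   length(unique(oracleCanonical(r, 27))))
  expect_true(all(sk@multiplicities == 10L))
})

test_that("1x error-free coverage with m=2 exercises the insufficient path", {
  set.seed(37)
  g <- randomSeq(5000)                 # every k-mer seen once: nothing retained
  expect_error(sketchReads(g, k = 27, s = 1000, m = 2), "insufficient k-mers")
  expect_error(sketchReads("ACGT", k = 27), "insufficient k-mers")
})

test_that("retained distinct count matches exact k-mer counting at 20x", {
  set.seed(39)
  g <- randomSeq(10000)
  starts <- sample(1:9500, 400, replace = TRUE)   # ~20x coverage of 10 kb
  reads <- substring(g, starts, pmin(starts + 499, 10000))
  sk <- sketchReads(reads, k = 27, s = 10^6, m = 1)  # oversized: exact regime
  truth <- length(unique(unlist(lapply(reads, oracleCanonical, k = 27))))
  expect_identical(length(sk@hashes), truth)
  expect_identical(estimateGenomeSize(sk), as.numeric(truth))  # unsaturated: exact
})

test_that("the bottom-s estimator recovers a known k-mer cardinality", {
  set.seed(41)
  g <- randomSeq(60000)
  reads <- rep(substring(g, seq(1, 59001, by = 500),
                         seq(1000, 60000, by = 500)), 3)
  exact <- sketchReads(reads, k = 21, s = 10^6, m = 2)
  truth <- length(exact@hashes)
  sk <- sketchReads(reads, k = 21, s = 1000, m = 2)
  expect_identical(length(sk@hashes), 1000L)       # saturated
  est <- estimateGenomeSize(sk)
  expect_lt(abs(est - truth) / truth, 0.10)
})

test_that("disjoint genome halves roughly double the estimate", {
  set.seed(43)
  gA <- randomSeq(50000); gB <- randomSeq(50000)
  covReads <- function(g) rep(substring(g, seq(1, 49001, by = 1000),
                                        seq(1000, 50000, by = 1000)), 2)
  estA <- estimateGenomeSize(sketchReads(covReads(gA), s = 1000, m = 2))
  estAB <- estimateGenomeSize(sketchReads(c(covReads(gA), covReads(gB)),
                                          s = 1000, m = 2))
  expect_gt(estAB / estA, 1.7)
  expect_lt(estAB / estA, 2.3)
})

test_that("coverage estimate is the mean retained multiplicity", {
  set.seed(45)
  r <- randomSeq(300)
  sk <- sketchReads(rep(r, 7), k = 27, s = 1000, m = 2)
  expect_equal(estimateCoverage(sk), 7)
  g <- randomSeq(50000)
  set.seed(46)
  starts <- sample(1:48000, 15 * 25, replace = TRUE)  # ~15x by 2 kb reads
  reads <- substring(g, starts, pmin(starts + 1999, 50000))
  est <- estimateCoverage(sketchReads(reads, k = 27, s = 1000, m = 2))
  expect_gt(est, 12); expect_lt(est, 18)
})

test_that("with m=2, errored reads raise the estimate above the naive mean", {
  set.seed(47)
  g <- randomSeq(20000)
  starts <- sample(1:19000, 200, replace = TRUE)
  reads <- substring(g, starts, pmin(starts + 999, 20000))
  noisy <- vapply(reads, function(s) {          # ~3% substitutions
    ch <- strsplit(s, "")[[1]]
    pos <- which(runif(length(ch)) < 0.03)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  m2 <- estimateCoverage(sketchReads(noisy, s = 1000, m = 2))
  m1 <- estimateCoverage(sketchReads(noisy, s = 1000, m = 1))
  expect_gt(m2, m1)                 # error singletons suppressed
})
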
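# size of the truncated hash space (53 bits: every value is an exact double)
HASH_SPACE <- 2^53

#' @title Bottom-s MinHash sketch of canonical k-mers
#'
#' @description A uniform random sample of the distinct canonical k-mers of
#' a read set, obtained by hashing every k-mer with a fixed well-mixed
#' 64-bit hash (splitmix64 finalizer, truncated to 53 bits) and keeping
#' the \code{s} smallest hash values among k-mers seen at least \code{m}
#' times. The multiplicity of each retained k-mer is recorded. For read
#' input \code{m = 2} suppresses sequencing-error k-mers, which are
#' overwhelmingly singletons; for assembled (FASTA) input use
#' \code{m = 1}.
#'
#' @slot k k-mer size (default 27).
#' @slot s sketch size (default 1000).
#' @slot m minimum copy number for retention.
#' @slot hashes the retained hash values, strictly increasing.
#' @slot multiplicities occurrence count per retained k-mer.
#' @slot distinctRetained exact number of distinct canonical k-mers with
#'   multiplicity >= m (known exactly at desk scale).
#' @slot seed hash seed.
#' @export
setClass("MinHashSketch", representation(
  k = "integer", s = "integer", m = "integer",
  hashes = "numeric", multiplicities = "integer",
  distinctRetained = "numeric", seed = "numeric"))

setValidity("MinHashSketch", function(object) {
  if (length(object@hashes) > object@s) return("more hashes than sketch size")
  if (length(object@hashes) != length(object@multiplicities)) {
    return("hashes and multiplicities differ in length")
  }
  if (is.unsorted(object@hashes, strictly = TRUE)) {
    return("hashes must be strictly increasing")
  }
  if (length(object@multiplicities) && any(object@multiplicities < object@m)) {
    return("retained multiplicities below the copy threshold m")
  }
  TRUE
})

setMethod("show", "MinHashSketch", function(object) {
  cat("MinHashSketch: k=", object@k, " s=", object@s, " m=", object@m,
      " | ", length(object@hashes), " hashes (",
      format(object@distinctRetained, big.mark = ","),
      " distinct k-mers retained)\n", sep = "")
})

#' Canonical k-mers of a sequence
#'
#' Every window of length \code{k} containing no non-ACGT letter is
#' emitted as the lexicographic minimum of the k-mer and its reverse
#' complement. Reference implementation at R level; the sketch itself
#' counts k-mers in compiled code.
#'
#' @param sequence a single character string.
#' @param k k-mer size.
#' @return character vector of canonical k-mers, one per valid window in
#'   order (a sequence shorter than \code{k} yields none).
#' @examples
#' canonicalKmers("AAAA", 4)  # "AAAA" (revcomp "TTTT" is larger)
#' @export
canonicalKmers <- function(sequence, k) {
  stopifnot(length(sequence) == 1L, k >= 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(sequence, starts, starts + k - 1L)
  rcFull <- chartr("ACGT", "TGCA", paste(rev(strsplit(sequence, "")[[1L]]),
                                         collapse = ""))
  rev <- substring(rcFull, n - starts - k + 2L, n - starts + 1L)
  keep <- !grepl("[^ACGT]", fwd)
  fwd <- fwd[keep]; rev <- rev[keep]
  ifelse(fwd <= rev, fwd, rev)
}

#' Sketch a read set
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or character vector of sequences.
#' @param k k-mer size, default 27.
#' @param s sketch size, default 1000.
#' @param m minimum k-mer copy number, default 2 (use 1 for assembled
#'   input).
#' @param seed hash seed (fixed default; identical inputs and seed give an
#'   identical sketch).
#' @return a [MinHashSketch-class] object.
#' @export
sketchReads <- function(reads, k = 27, s = 1000, m = 2, seed = 42) {
  seqs <- as.character(reads)
  res <- .sketchKmersCpp(seqs, as.integer(k), as.integer(s),
                         as.integer(m), as.numeric(seed))
  if (res$total_kmers == 0) {
    stop("insufficient k-mers: no read is at least k = ", k, " bases long",
         call. = FALSE)
  }
  if (length(res$hashes) == 0L) {
    stop("insufficient k-mers: no canonical k-mer reached the copy ",
         "threshold m = ", m, call. = FALSE)
  }
  new("MinHashSketch", k = as.integer(k), s = as.integer(s),
      m = as.integer(m), hashes = res$hashes,
      multiplicities = res$multiplicities,
      distinctRetained = res$distinct_retained, seed = as.numeric(seed))
}

#' Reference-free genome-size estimate from a sketch
#'
#' For a saturated sketch the distinct canonical k-mer cardinality is
#' estimated with the bottom-s (k-minimum-values) formula
#' \eqn{(s - 1) \cdot H / h_s}, where H is the hash-space size and
#' \eqn{h_s} the largest retained hash; an unsaturated sketch holds every
#' retained k-mer, so the exact distinct count is returned. For k well
#' above the repeat scale the distinct k-mer count approximates the total
#' (community-wide) genome length in bases.
#'
#' @param sketch a [MinHashSketch-class].
#' @return estimated genome size in bases.
#' @export
estimateGenomeSize <- function(sketch) {
  nh <- length(sketch@hashes)
  if (nh == 0L) stop("empty sketch", call. = FALSE)
  if (nh < sketch@s) {
    return(as.numeric(nh))
  }
  (nh - 1) * HASH_SPACE / sketch@hashes[nh]
}

#' Reference-free coverage estimate from a sketch
#'
#' The sketch is a uniform random sample of distinct canonical k-mers, so
#' the mean multiplicity of the retained k-mers estimates the per-k-mer
#' sequencing depth, which tracks base coverage up to the edge factor
#' (L - k + 1)/L of read length L.
#'
#' @param sketch a [MinHashSketch-class].
#' @return estimated fold coverage.
#' @export
estimateCoverage <- function(sketch) {
  if (length(sketch@multiplicities) == 0L) stop("empty sketch", call. = FALSE)
  mean(sketch@multiplicities)
}
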
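#' @title Read quality-control parameters
#'
#' @description The QC stage reproduces the default behaviour of the
#' standard short/long-read quality filter with duplicate removal: a read
#' is kept when (i) the fraction of bases below \code{qualified_phred} is
#' at most \code{max_unqualified_fraction}, (ii) it has at most
#' \code{max_n_bases} N bases, (iii) it is at least \code{min_length}
#' bases, and (iv), when \code{dedup} is on, its exact sequence has not
#' been seen earlier in the file (first occurrence kept). Adapter and
#' quality trimming are deliberately not performed: input is long-read
#' rapid-kit data where trimming is handled upstream.
#'
#' @slot qualified_phred phred threshold defining a "qualified" base
#'   (default 15).
#' @slot max_unqualified_fraction maximum tolerated fraction of
#'   unqualified bases (default 0.40).
#' @slot max_n_bases maximum N count (default 5).
#' @slot min_length minimum read length in bases (default 15).
#' @slot dedup drop exact duplicate sequences (default TRUE).
#' @export
setClass("QcParams", representation(
  qualified_phred = "numeric",
  max_unqualified_fraction = "numeric",
  max_n_bases = "numeric",
  min_length = "numeric",
  dedup = "logical"))

setValidity("QcParams", function(object) {
  if (object@qualified_phred < 0 || object@max_n_bases < 0 ||
      object@min_length < 0 || object@max_unqualified_fraction < 0) {
    return("all thresholds must be >= 0")
  }
  if (object@max_unqualified_fraction > 1) {
    return("max_unqualified_fraction must be <= 1")
  }
  TRUE
})

#' Build QC parameters
#'
#' @param qualified_phred,max_unqualified_fraction,max_n_bases,min_length,dedup
#'   see [QcParams-class] for meanings and defaults.
#' @return a [QcParams-class] object.
#' @export
qcParams <- function(qualified_phred = 15, max_unqualified_fraction = 0.40,
                     max_n_bases = 5, min_length = 15, dedup = TRUE) {
  new("QcParams", qualified_phred = qualified_phred,
      max_unqualified_fraction = max_unqualified_fraction,
      max_n_bases = max_n_bases, min_length = min_length, dedup = dedup)
}

setMethod("show", "QcParams", function(object) {
  cat("QcParams: qualified_phred=", object@qualified_phred,
      ", max_unqualified_fraction=", object@max_unqualified_fraction,
      ", max_n_bases=", object@max_n_bases,
      ", min_length=", object@min_length,
      ", dedup=", object@dedup, "\n", sep = "")
})

#' Error-probability-averaged mean Q score
#'
#' The mean Q score of a read is not the arithmetic mean of its per-base
#' phred values: phred is a log scale, so the per-base error probabilities
#' are averaged first and converted back, \eqn{-10 \log_{10}(\bar p)}.
#' This matches how basecallers report \code{mean_qscore_template} and is
#' used for the manifest's \code{read_qscore} when no sequencing summary
#' is supplied.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return numeric vector, one mean Q per read.
#' @examples
#' fq <- newFastqSet("r1", "ACGT", "+5+5")   # alternating q10 / q20
#' @export
meanQscore <- function(reads) {
  if (any(Biostrings::width(reads) == 0L)) {
    stop("cannot compute a mean Q score for an empty quality string",
         call. = FALSE)
  }
  q <- qualityScores(reads)
  p <- 10^(-q / 10)
  -10 * log10(vapply(p, mean, numeric(1)))
}

#' Quality-filter a read set
#'
#' Applies the four rules of [QcParams-class] and returns the kept reads,
#' the per-read verdict and sample-wide statistics. The verdict for every
#' input read is recorded: a read failing any threshold is a filter
#' failure; a read passing the thresholds whose exact sequence occurred
#' earlier is a removed duplicate. Conservation holds:
#' \code{reads_in == reads_out + failures + duplicates_removed}.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param params a [QcParams-class] object.
#' @return list with \code{kept} (the surviving read set),
#'   \code{status} (named logical over all input reads) and \code{stats}
#'   (list: \code{total_bases}, \code{total_fastp_bases},
#'   \code{mean_read_length}, \code{reads_in}, \code{reads_out},
#'   \code{failures}, \code{duplicates_removed}).
#' @export
qcFilter <- function(reads, params = qcParams()) {
  validObject(params)
  n <- length(reads)
  len <- Biostrings::width(reads)
  if (n == 0L) {
    stats <- list(total_bases = 0, total_fastp_bases = 0,
                  mean_read_length = 0, reads_in = 0L, reads_out = 0L,
                  failures = 0L, duplicates_removed = 0L)
    return(list(kept = reads, status = setNames(logical(0), character(0)),
                stats = stats))
  }
  q <- qualityScores(reads)
  fracUnqualified <- vapply(q, function(v) mean(v < params@qualified_phred),
                            numeric(1))
  nCount <- as.vector(Biostrings::letterFrequency(reads, "N"))
  passRules <- fracUnqualified <= params@max_unqualified_fraction &
    nCount <= params@max_n_bases &
    len >= params@min_length
  isDup <- if (params@dedup) duplicated(as.character(reads)) else rep(FALSE, n)
  keep <- passRules & !isDup
  status <- setNames(keep, names(reads))
  kept <- reads[keep]
  stats <- list(
    total_bases = sum(as.numeric(len)),
    total_fastp_bases = sum(as.numeric(len[keep])),
    mean_read_length = if (any(keep)) sum(as.numeric(len[keep])) / sum(keep) else 0,
    reads_in = n,
    reads_out = sum(keep),
    failures = sum(!passRules),
    duplicates_removed = sum(passRules & isDup))
  list(kept = kept, status = status, stats = stats)
}
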
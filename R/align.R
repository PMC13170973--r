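#' @title External aligner configuration
#'
#' @description Read mapping is delegated to an external seed-chain-extend
#' aligner (minimap2). The long-read preset (\code{-ax map-ont}) is used
#' for single-end nanopore reads and the short-read preset (\code{-ax sr})
#' for paired Illumina input; the seed k-mer size is fixed at 15, the
#' community-established choice for noisy long reads. When no aligner is
#' available, alignments can be supplied directly as SAM via
#' [readSamRecords()] / the \code{sam} argument of [runAnalyze()].
#'
#' @slot preset \code{"long_read_ont"} or \code{"short_read_paired"}.
#' @slot kmer seed k-mer size (default 15).
#' @slot executable aligner executable name or path (default
#'   \code{"minimap2"}).
#' @export
setClass("AlignerConfig", representation(
  preset = "character", kmer = "numeric", executable = "character"))

setValidity("AlignerConfig", function(object) {
  if (!object@preset %in% c("long_read_ont", "short_read_paired")) {
    return("preset must be 'long_read_ont' or 'short_read_paired'")
  }
  if (object@kmer < 1) return("kmer must be >= 1")
  TRUE
})

#' Build an aligner configuration
#'
#' @param preset \code{"long_read_ont"} (default) or
#'   \code{"short_read_paired"}.
#' @param kmer seed k-mer size, default 15.
#' @param executable aligner binary, default \code{"minimap2"}.
#' @return an [AlignerConfig-class] object.
#' @export
alignerConfig <- function(preset = "long_read_ont", kmer = 15,
                          executable = "minimap2") {
  new("AlignerConfig", preset = preset, kmer = kmer, executable = executable)
}

#' Is the configured external aligner available?
#' @param config an [AlignerConfig-class] object.
#' @return logical.
#' @export
alignerAvailable <- function(config = alignerConfig()) {
  nzchar(Sys.which(config@executable))
}

#' Map reads to a reference with the external aligner
#'
#' @param fastq path to the (quality-filtered) reads; for
#'   \code{short_read_paired} a length-2 vector of mate files.
#' @param reference path to the multi-sequence reference FASTA.
#' @param outSam output SAM path.
#' @param config an [AlignerConfig-class] object.
#' @return \code{outSam}, invisibly.
#' @export
alignReads <- function(fastq, reference, outSam, config = alignerConfig()) {
  validObject(config)
  if (!alignerAvailable(config)) {
    stop("external aligner '", config@executable, "' not found on PATH; ",
         "supply alignments directly as SAM (runAnalyze(sam = ...))",
         call. = FALSE)
  }
  preset <- switch(config@preset,
                   long_read_ont = "map-ont",
                   short_read_paired = "sr")
  errFile <- tempfile("aligner-stderr-")
  status <- system2(config@executable,
                    c("-ax", preset, "-k", format(config@kmer),
                      shQuote(reference), shQuote(fastq)),
                    stdout = outSam, stderr = errFile)
  if (status != 0L) {
    stop("aligner exited with status ", status, ":\n",
         paste(readLines(errFile, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  }
  invisible(outSam)
}
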
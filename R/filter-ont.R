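#' @title Read-subsetting criteria over the sequencing summary
#'
#' @description All criteria are optional; an absent bound imposes no
#' constraint. Bounds are inclusive on both ends, so the conventional AS
#' channel split is \code{min_ch = 1 (or 0), max_ch = 256} for the test
#' half of a 512-channel flow cell and \code{min_ch = 257, max_ch = 512}
#' for the control half. The \code{decisions} criterion matches raw
#' \code{end_reason} tokens (e.g. \code{signal_positive}), not the derived
#' decision classes.
#'
#' @slot min_ch,max_ch channel bounds.
#' @slot min_len,max_len basecalled length bounds
#'   (\code{sequence_length_template}).
#' @slot min_q,max_q mean Q score bounds.
#' @slot start_time_min,start_time_max window on the read start time
#'   (seconds from run start).
#' @slot min_duration,max_duration bounds on the per-read sequencing
#'   duration (seconds).
#' @slot decisions raw end_reason tokens to keep (case-insensitive);
#'   empty means no constraint.
#' @export
setClass("FilterCriteria", representation(
  min_ch = "numeric", max_ch = "numeric",
  min_len = "numeric", max_len = "numeric",
  min_q = "numeric", max_q = "numeric",
  start_time_min = "numeric", start_time_max = "numeric",
  min_duration = "numeric", max_duration = "numeric",
  decisions = "character"))

setValidity("FilterCriteria", function(object) {
  pairs <- list(c("min_ch", "max_ch"), c("min_len", "max_len"),
                c("min_q", "max_q"), c("start_time_min", "start_time_max"),
                c("min_duration", "max_duration"))
  for (p in pairs) {
    lo <- slot(object, p[1]); hi <- slot(object, p[2])
    if (length(lo) && length(hi) && lo > hi) {
      return(paste0("invalid criteria: ", p[1], " (", lo, ") > ",
                    p[2], " (", hi, ")"))
    }
  }
  TRUE
})

#' Build read-filter criteria
#'
#' @param min_ch,max_ch,min_len,max_len,min_q,max_q,start_time_min,start_time_max,min_duration,max_duration
#'   optional inclusive bounds (\code{NULL} = no constraint).
#' @param decisions optional character vector of raw end_reason tokens.
#' @return a [FilterCriteria-class] object.
#' @examples
#' controlHalf <- filterCriteria(min_ch = 257, max_ch = 512)
#' @export
filterCriteria <- function(min_ch = NULL, max_ch = NULL,
                           min_len = NULL, max_len = NULL,
                           min_q = NULL, max_q = NULL,
                           start_time_min = NULL, start_time_max = NULL,
                           min_duration = NULL, max_duration = NULL,
                           decisions = NULL) {
  num <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  new("FilterCriteria",
      min_ch = num(min_ch), max_ch = num(max_ch),
      min_len = num(min_len), max_len = num(max_len),
      min_q = num(min_q), max_q = num(max_q),
      start_time_min = num(start_time_min), start_time_max = num(start_time_max),
      min_duration = num(min_duration), max_duration = num(max_duration),
      decisions = if (is.null(decisions)) character(0) else as.character(decisions))
}

setMethod("show", "FilterCriteria", function(object) {
  cat("FilterCriteria\n")
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v)) cat("  ", s, ": ", paste(v, collapse = ","), "\n", sep = "")
  }
})

#' Match reads against filter criteria
#'
#' A read is selected when every present criterion holds for at least one
#' of its summary rows: subsetting is all-or-nothing per read id, so a
#' strand re-evaluated across several pore events is kept if any event
#' matches.
#'
#' @param summary data.frame from [readSequencingSummary()].
#' @param criteria a [FilterCriteria-class] object.
#' @return character vector of matching read ids (unique, in first-seen
#'   order).
#' @export
matchReads <- function(summary, criteria) {
  validObject(criteria)
  ok <- rep(TRUE, nrow(summary))
  bound <- function(ok, value, lo, hi) {
    if (length(lo)) ok <- ok & value >= lo
    if (length(hi)) ok <- ok & value <= hi
    ok
  }
  ok <- bound(ok, summary$channel, criteria@min_ch, criteria@max_ch)
  ok <- bound(ok, summary$sequence_length_template,
              criteria@min_len, criteria@max_len)
  ok <- bound(ok, summary$mean_qscore_template, criteria@min_q, criteria@max_q)
  ok <- bound(ok, summary$start_time,
              criteria@start_time_min, criteria@start_time_max)
  ok <- bound(ok, summary$duration, criteria@min_duration, criteria@max_duration)
  if (length(criteria@decisions)) {
    ok <- ok & tolower(trimws(summary$end_reason)) %in%
      tolower(trimws(criteria@decisions))
  }
  unique(summary$read_id[ok])
}

#' Subset a read set by read id
#'
#' Output preserves input order. Ids in \code{keep} that are absent from
#' the input are not an error; their count is reported and recorded in
#' \code{metadata()}.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param keep character vector of read ids to retain.
#' @return the matching subset, input order preserved.
#' @export
subsetFastq <- function(reads, keep) {
  out <- reads[names(reads) %in% keep]
  nMissing <- length(setdiff(keep, names(reads)))
  if (nMissing > 0) {
    message(nMissing, " read id(s) in the keep list were not present in the FASTQ")
  }
  S4Vectors::metadata(out)$missing_ids <- nMissing
  out
}

#' Filter a run by sequencing-summary criteria
#'
#' The filter stage of the pipeline: evaluates \code{criteria} against the
#' sequencing summary, writes the curated read list (one read id per line)
#' and the subset FASTQ. Typically used to split an AS flow cell into its
#' test and control channel halves.
#'
#' @param seqSummary path to the sequencing summary TSV, or a parsed
#'   data.frame.
#' @param inputFastq path to the basecalled FASTQ, or a parsed read set.
#' @param outputPrefix output path prefix; writes
#'   \code{<prefix>_read_list.txt} and \code{<prefix>.fastq}.
#' @param criteria a [FilterCriteria-class] object.
#' @return (invisibly) a list with \code{read_ids}, \code{fastq},
#'   \code{read_list} and \code{n_reads}.
#' @export
filterONT <- function(seqSummary, inputFastq, outputPrefix, criteria) {
  summary <- if (is.character(seqSummary)) readSequencingSummary(seqSummary)
             else seqSummary
  reads <- if (is.character(inputFastq)) readFastq(inputFastq) else inputFastq
  ids <- matchReads(summary, criteria)
  listPath <- paste0(outputPrefix, "_read_list.txt")
  fastqPath <- paste0(outputPrefix, ".fastq")
  writeLines(ids, listPath)
  kept <- subsetFastq(reads, ids)
  writeFastq(kept, fastqPath)
  invisible(list(read_ids = ids, fastq = fastqPath, read_list = listPath,
                 n_reads = length(kept)))
}
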
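# the three approximate AS decision classes, in reporting order
decisionClasses <- c("stop_receiving", "unblocked", "no_decision")

#' Classify a raw end_reason token into an AS decision class
#'
#' The sequencing summary does not store the ReadUntil API's per-read
#' decisions, so pore-level termination reasons are mapped to three
#' approximate classes: \code{signal_positive} means the strand was
#' sequenced to completion (\code{stop_receiving}, accept);
#' \code{data_service_unblock_mux_change} records an active ejection of
#' the strand by voltage reversal (\code{unblocked}, reject);
#' \code{signal_negative} and \code{unblock_mux_change} indicate no
#' explicit accept/reject action was taken (\code{no_decision}). Matching
#' is case-insensitive with surrounding whitespace trimmed -- summary
#' files capitalise these tokens inconsistently. Any other token maps to
#' \code{"unknown"} and is excluded from percentage denominators
#' downstream.
#'
#' @param end_reason character vector of raw tokens.
#' @return character vector over \code{stop_receiving}, \code{unblocked},
#'   \code{no_decision}, \code{unknown}.
#' @examples
#' classifyEndReason(c("signal_positive", "Signal_positive",
#'                     "data_service_unblock_mux_change", "mux_change"))
#' @export
classifyEndReason <- function(end_reason) {
  tok <- tolower(trimws(end_reason))
  out <- rep("unknown", length(tok))
  out[tok == "signal_positive"] <- "stop_receiving"
  out[tok == "data_service_unblock_mux_change"] <- "unblocked"
  out[tok %in% c("signal_negative", "unblock_mux_change")] <- "no_decision"
  out
}

#' Time-binned decision distribution (independent bins)
#'
#' Each pore event falls in the left-closed right-open bin containing its
#' start time; bins are contiguous from 0 to the last start time.
#' Percentages within a bin are computed over classified events only;
#' events with an unknown end reason are counted separately (attribute
#' \code{"unknown"}) and excluded from both counts and percentages.
#' Duplicate summary rows for a read are binned per occurrence: each pore
#' event is a decision event.
#'
#' @param rows data.frame with \code{start_time} and \code{decision}
#'   columns (manifest rows, or a sequencing summary with
#'   \code{end_reason} renamed).
#' @param binWidth bin width in seconds (e.g. 900 for 15-minute bins).
#' @return data.frame with \code{bin_start}, \code{bin_end},
#'   \code{read_count} and \code{pct_stop_receiving},
#'   \code{pct_unblocked}, \code{pct_no_decision} (each 0 for empty
#'   bins; summing to 100 otherwise). Zero rows when nothing could be
#'   classified.
#' @export
binDecisions <- function(rows, binWidth) {
  if (binWidth <= 0) stop("binWidth must be > 0", call. = FALSE)
  if ("decision" %in% colnames(rows)) dec <- rows$decision
  else dec <- rows$end_reason
  cls <- classifyEndReason(dec)
  t <- rows$start_time
  keep <- cls != "unknown" & !is.na(t)
  nUnknown <- sum(cls == "unknown")
  cls <- cls[keep]; t <- t[keep]
  if (!length(cls)) {
    out <- emptyBins()
    attr(out, "unknown") <- nUnknown
    return(out)
  }
  bin <- floor(t / binWidth)
  nBins <- max(bin) + 1L
  counts <- vapply(decisionClasses, function(cl)
    tabulate(bin[cls == cl] + 1L, nbins = nBins), integer(nBins))
  counts <- matrix(counts, nrow = nBins,
                   dimnames = list(NULL, decisionClasses))
  total <- rowSums(counts)
  pct <- 100 * counts / ifelse(total > 0, total, 1)
  out <- data.frame(
    bin_start = (seq_len(nBins) - 1L) * binWidth,
    bin_end = seq_len(nBins) * binWidth,
    read_count = as.integer(total),
    pct_stop_receiving = pct[, "stop_receiving"],
    pct_unblocked = pct[, "unblocked"],
    pct_no_decision = pct[, "no_decision"])
  attr(out, "unknown") <- nUnknown
  out
}

emptyBins <- function() {
  data.frame(bin_start = numeric(0), bin_end = numeric(0),
             read_count = integer(0), pct_stop_receiving = numeric(0),
             pct_unblocked = numeric(0), pct_no_decision = numeric(0))
}

#' Cumulative decision distribution over time bins
#'
#' Bin i of the output aggregates the events of input bins 1..i: counts
#' are summed and percentages recomputed over the union, so the final
#' cumulative bin equals the whole-run decision distribution.
#'
#' @param bins independent bins from [binDecisions()].
#' @return data.frame with the same columns.
#' @export
cumulateBins <- function(bins) {
  if (!nrow(bins)) return(bins)
  classCounts <- vapply(decisionClasses, function(cl)
    bins[[paste0("pct_", cl)]] * bins$read_count / 100, numeric(nrow(bins)))
  classCounts <- matrix(classCounts, nrow = nrow(bins),
                        dimnames = list(NULL, decisionClasses))
  cum <- apply(classCounts, 2, cumsum)
  cum <- matrix(cum, nrow = nrow(bins), dimnames = list(NULL, decisionClasses))
  total <- rowSums(cum)
  pct <- 100 * cum / ifelse(total > 0, total, 1)
  data.frame(
    bin_start = bins$bin_start[1L],
    bin_end = bins$bin_end,
    read_count = as.integer(round(total)),
    pct_stop_receiving = pct[, "stop_receiving"],
    pct_unblocked = pct[, "unblocked"],
    pct_no_decision = pct[, "no_decision"])
}
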
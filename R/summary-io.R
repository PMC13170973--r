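# Required columns of a Guppy/Dorado sequencing summary. Extra columns are
# ignored silently; column order in the file is free.
summaryRequiredCols <- c("read_id", "channel", "start_time", "duration",
                         "sequence_length_template", "mean_qscore_template",
                         "end_reason")

#' Read an ONT sequencing summary table
#'
#' The sequencing summary is the TSV emitted during basecalling (Guppy or
#' Dorado), one row per pore-level read event: channel, start time and
#' duration (seconds from run start), basecalled length, mean Q score and
#' the \code{end_reason} recording why the pore stopped sequencing the
#' strand. A read id may appear in more than one row when a strand was
#' re-evaluated before a final decision.
#'
#' @param path TSV with a header row (plain or gzip). Required columns may
#'   appear in any order; extra columns are ignored.
#' @return a \code{data.frame} with the seven required columns, rows in
#'   file order.
#' @export
readSequencingSummary <- function(path) {
  df <- read.delim(text = readTextLines(path), header = TRUE, sep = "\t",
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  missing <- setdiff(summaryRequiredCols, colnames(df))
  if (length(missing)) {
    stop("sequencing summary is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, summaryRequiredCols, drop = FALSE]
  numCols <- c("channel", "start_time", "duration",
               "sequence_length_template", "mean_qscore_template")
  for (col in numCols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("sequencing summary: cannot parse numeric value '",
           df[[col]][bad[1L]], "' in column '", col, "' at line ",
           bad[1L] + 1L, call. = FALSE)   # +1 for the header line
    }
    df[[col]] <- v
  }
  df$channel <- as.integer(df$channel)
  if (nrow(df)) {
    if (any(df$duration < 0, na.rm = TRUE) ||
        any(df$start_time < 0, na.rm = TRUE)) {
      stop("sequencing summary: negative start_time or duration",
           call. = FALSE)
    }
    if (any(!nzchar(df$end_reason))) {
      stop("sequencing summary: empty end_reason at line ",
           which(!nzchar(df$end_reason))[1L] + 1L, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a sequencing summary table
#'
#' @param summary data.frame as returned by [readSequencingSummary()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSequencingSummary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
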
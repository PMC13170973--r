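#' Read a 4-line FASTQ file with strict validation
#'
#' Basecaller output is 4-line FASTQ (no line wrapping). Each record is
#' checked for its format indicators -- \code{@} on line one, \code{+} on
#' line three -- and for agreement between sequence length and quality
#' string length. In strict mode (the default, and the behaviour of the
#' analyze stage) the first malformed record aborts the whole parse;
#' invalid files halt the process rather than yielding partial results.
#'
#' @param path FASTQ file, plain or gzip (gzip is detected from the magic
#'   bytes, not the extension).
#' @param strict abort on the first malformed record (\code{TRUE}) or drop
#'   malformed records with a warning (\code{FALSE}).
#' @return A [Biostrings::QualityScaledDNAStringSet] named by read id (the
#'   first whitespace-delimited token of the header). The full header and
#'   the line-3 remainder are kept in \code{mcols()} so that
#'   \code{\link{writeFastq}} round-trips well-formed input byte-for-byte.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1 desc", "ACGT", "+", "IIII"), fq)
#' reads <- readFastq(fq)
#' names(reads)      # "r1"
#' width(reads)      # 4
#' @export
readFastq <- function(path, strict = TRUE) {
  lines <- readTextLines(path)
  # trailing blank lines are tolerated; internal blanks are format errors
  while (length(lines) && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(newFastqSet(character(), character(), character(), character()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error: file does not contain complete 4-line records (",
         length(lines), " lines)", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[(idx - 1L) * 4L + 1L]
  seqs <- lines[(idx - 1L) * 4L + 2L]
  plus <- lines[(idx - 1L) * 4L + 3L]
  qual <- lines[(idx - 1L) * 4L + 4L]

  badAt <- !startsWith(hdr, "@")
  badPlus <- !startsWith(plus, "+")
  badLen <- nchar(seqs) != nchar(qual)
  bad <- badAt | badPlus | badLen
  if (any(bad)) {
    i <- which(bad)[1L]
    msg <- if (badAt[i]) {
      paste0("record ", i, ": expected '@' on line 1 of the record")
    } else if (badPlus[i]) {
      paste0("record ", i, ": expected '+' on line 3 of the record")
    } else {
      paste0("record ", i, " (", firstToken(sub("^@", "", hdr[i])),
             "): sequence length ", nchar(seqs[i]),
             " does not match quality length ", nchar(qual[i]))
    }
    if (strict) stop("FASTQ format error: ", msg, call. = FALSE)
    warning("FASTQ: dropped ", sum(bad), " malformed record(s); first: ",
            msg, call. = FALSE)
    keep <- !bad
    hdr <- hdr[keep]; seqs <- seqs[keep]; plus <- plus[keep]; qual <- qual[keep]
  }
  ids <- firstToken(sub("^@", "", hdr))
  if (any(ids == "")) {
    stop("FASTQ format error: record ", which(ids == "")[1L],
         " has an empty read id", call. = FALSE)
  }
  newFastqSet(ids, seqs, qual,
              desc = sub("^@", "", hdr), plus = sub("^\\+", "", plus))
}

#' Construct the in-memory read container from parallel vectors
#'
#' Mainly useful for building small read sets programmatically (tests,
#' examples); [readFastq()] is the usual entry point.
#'
#' @param ids read ids.
#' @param seqs sequences over A/C/G/T/N.
#' @param qual phred+33 quality strings.
#' @param desc full header text (defaults to the ids).
#' @param plus line-3 remainder after \code{+} (defaults to empty).
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
newFastqSet <- function(ids, seqs, qual, desc = ids, plus = rep("", length(ids))) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(toupper(seqs)),
    Biostrings::PhredQuality(qual))
  names(x) <- ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(desc = desc, plus = plus)
  x
}

#' Write reads to a 4-line FASTQ file
#'
#' Inverse of [readFastq()]: the stored full header and line-3 remainder are
#' emitted verbatim, so parse-then-write is byte-identical for well-formed
#' input.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] as returned by
#'   [readFastq()] (plain \code{QualityScaledDNAStringSet}s are accepted;
#'   the name is then used as the header).
#' @param path output file; written gzipped when it ends in \code{.gz}.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
  mc <- S4Vectors::mcols(reads)
  desc <- if (!is.null(mc) && "desc" %in% colnames(mc)) mc$desc else names(reads)
  plus <- if (!is.null(mc) && "plus" %in% colnames(mc)) mc$plus else rep("", length(reads))
  out <- character(4L * length(reads))
  if (length(reads)) {
    i <- seq_along(reads)
    out[(i - 1L) * 4L + 1L] <- paste0("@", desc)
    out[(i - 1L) * 4L + 2L] <- as.character(reads)
    out[(i - 1L) * 4L + 3L] <- paste0("+", plus)
    out[(i - 1L) * 4L + 4L] <- as.character(Biostrings::quality(reads))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Per-base phred scores of a read set
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return an [IRanges::IntegerList], one element per read.
#' @export
qualityScores <- function(reads) {
  methods::as(Biostrings::quality(reads), "IntegerList")
}
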
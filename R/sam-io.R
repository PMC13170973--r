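#' Read alignment records from a SAM (or BAM) file
#'
#' Parsing is delegated to htslib via \pkg{Rsamtools}; text SAM input is
#' converted to BAM in a temporary file first. The \code{@SQ} header must
#' declare every mapped target; its lengths are retained (attribute
#' \code{"seqlengths"}) for cross-checking against the reference set.
#'
#' @param path SAM text file, or a BAM file (detected by magic bytes).
#' @return a \code{data.frame} with columns \code{read_id}, \code{flag},
#'   \code{taxon_id} (the unmapped marker \code{"*"} for flag-0x4 records),
#'   \code{pos} (1-based leftmost), \code{mapq}, \code{cigar} and
#'   \code{read_length} (query length where stored, else \code{NA}), plus a
#'   \code{"seqlengths"} attribute naming the \code{@SQ} lengths.
#' @export
readSamRecords <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file does not exist: ", path, call. = FALSE)
  }
  isBam <- isGzip(path)   # BAM is BGZF, which carries the gzip magic
  bam <- if (isBam) path else {
    checkSamHeader(path)
    tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) {
        stop("SAM format error in ", path, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "qwidth"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  unmapped <- bitwAnd(b$flag, 0x4L) != 0L
  taxon <- as.character(b$rname)
  taxon[unmapped | is.na(taxon)] <- "*"
  out <- data.frame(
    read_id = b$qname,
    flag = b$flag,
    taxon_id = taxon,
    pos = ifelse(unmapped, NA_integer_, b$pos),
    mapq = b$mapq,
    cigar = ifelse(unmapped, NA_character_, b$cigar),
    read_length = b$qwidth,
    stringsAsFactors = FALSE)
  attr(out, "seqlengths") <- hdr
  out
}

# light pre-scan of a text SAM: every mapped record's RNAME must appear in
# an @SQ header line (the spec'd error contract; htslib would also fail,
# but with a less actionable message)
checkSamHeader <- function(path) {
  lines <- readTextLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    rn <- vapply(f, function(x) x[3L], character(1))
    fl <- suppressWarnings(as.integer(vapply(f, function(x) x[2L], character(1))))
    mapped <- !is.na(fl) & bitwAnd(fl, 0x4L) == 0L & rn != "*"
    bad <- setdiff(unique(rn[mapped]), sn)
    if (length(bad)) {
      stop("SAM format error: reference name(s) absent from @SQ header: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Keep only primary alignment records
#'
#' Secondary (0x100) and supplementary (0x800) records are excluded so that
#' downstream per-taxon counting (mapped reads, mapped bases, depth) is
#' conserved: each mapped read contributes exactly once.
#'
#' @param alignments data.frame from [readSamRecords()].
#' @return the primary subset, same columns.
#' @export
selectPrimary <- function(alignments) {
  keep <- bitwAnd(alignments$flag, bitwOr(0x100L, 0x800L)) == 0L
  out <- alignments[keep, , drop = FALSE]
  mappedIds <- out$read_id[out$taxon_id != "*"]
  if (anyDuplicated(mappedIds)) {
    dup <- unique(mappedIds[duplicated(mappedIds)])
    stop("alignment data error: multiple primary mapped records for read(s): ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  attr(out, "seqlengths") <- attr(alignments, "seqlengths")
  rownames(out) <- NULL
  out
}

#' Reference bases covered by a CIGAR string
#'
#' Counts reference positions consumed by M/=/X operations. Deletions and
#' skips (D/N) advance along the reference but contribute no coverage;
#' insertions and clips consume no reference at all.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of covered reference bases.
#' @examples
#' alignedRefSpan(c("100M", "50M10D50M", "10S90M"))  # 100 100 90
#' @export
alignedRefSpan <- function(cigar) {
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) {
    stop("invalid CIGAR string: ", cigar[which(bad)[1L]], call. = FALSE)
  }
  ol <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = c("M", "=", "X"))
  vapply(ol, function(x) sum(x), integer(1))
}

# per-record IRanges of reference positions covered by M/=/X
cigarCoverRanges <- function(cigar, pos) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
}
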
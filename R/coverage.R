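#' Per-position depth of coverage for one taxon
#'
#' Depth at position i is the number of primary alignments whose M/=/X
#' CIGAR operations cover i. Deleted (D) and skipped (N) reference
#' positions are spanned but not covered; insertions and clips contribute
#' nothing. The accumulated depth mass equals the sum of
#' [alignedRefSpan()] over the alignments.
#'
#' @param alignments primary mapped records (one taxon) from
#'   [selectPrimary()].
#' @param taxonLength reference length in bases.
#' @return an [S4Vectors::Rle] of integer depths, length
#'   \code{taxonLength}.
#' @export
depthProfile <- function(alignments, taxonLength) {
  if (taxonLength <= 0) stop("taxonLength must be > 0", call. = FALSE)
  mapped <- alignments[alignments$taxon_id != "*", , drop = FALSE]
  if (length(unique(mapped$taxon_id)) > 1L) {
    stop("depthProfile expects alignments of a single taxon", call. = FALSE)
  }
  if (nrow(mapped) == 0L) {
    return(S4Vectors::Rle(0L, taxonLength))
  }
  rngList <- cigarCoverRanges(mapped$cigar, mapped$pos)
  rng <- unlist(rngList, use.names = FALSE)
  over <- max(IRanges::end(rng), 0L) > taxonLength
  if (over) {
    i <- which(vapply(rngList, function(r)
      length(r) && max(IRanges::end(r)) > taxonLength, logical(1)))[1L]
    stop("alignment data error: read '", mapped$read_id[i],
         "' overruns the reference (end ",
         max(IRanges::end(rngList[[i]])), " > length ", taxonLength, ")",
         call. = FALSE)
  }
  IRanges::coverage(rng, width = taxonLength)
}

#' Per-taxon aggregate coverage statistics
#'
#' @param depth depth profile from [depthProfile()].
#' @param readLengths full read lengths (bases) of the reads whose primary
#'   alignment is to this taxon. Mean read length is the mean of full read
#'   lengths, not aligned spans, so AS-truncated reads show up as short.
#' @param taxonId reference sequence id.
#' @param taxonLength reference length in bases.
#' @param threshold minimum depth X defining coverage breadth (a position
#'   counts as covered when depth >= X); default 1.
#' @return one-row \code{data.frame}: \code{taxon_id},
#'   \code{taxon_length}, \code{taxon_mean_coverage},
#'   \code{taxon_covered_bases_X}, \code{taxon_pct_covered_bases_X},
#'   \code{total_taxon_ref_mapped_bases}, \code{taxon_mean_read_length}
#'   (full precision; rounding is a rendering concern).
#' @export
taxonSummary <- function(depth, readLengths, taxonId, taxonLength,
                         threshold = 1) {
  if (taxonLength <= 0) stop("taxonLength must be > 0", call. = FALSE)
  if (threshold < 1) stop("coverage threshold must be >= 1", call. = FALSE)
  totalMapped <- sum(as.numeric(S4Vectors::runLength(depth)) *
                     as.numeric(S4Vectors::runValue(depth)))
  covered <- sum(as.numeric(
    S4Vectors::runLength(depth)[S4Vectors::runValue(depth) >= threshold]))
  data.frame(
    taxon_id = taxonId,
    taxon_length = taxonLength,
    taxon_mean_coverage = totalMapped / taxonLength,
    taxon_covered_bases_X = covered,
    taxon_pct_covered_bases_X = 100 * covered / taxonLength,
    total_taxon_ref_mapped_bases = totalMapped,
    taxon_mean_read_length = if (length(readLengths)) mean(readLengths) else 0,
    stringsAsFactors = FALSE)
}

#' Coverage statistics for every reference sequence
#'
#' Convenience loop over [depthProfile()] + [taxonSummary()]: one row per
#' reference taxon (zeros when nothing mapped) plus the \code{"*"} row for
#' unmapped reads, always last and all zeros.
#'
#' @param alignments primary records from [selectPrimary()].
#' @param reads the read set (used for full read lengths; alignment-stored
#'   lengths are the fallback for reads absent from it).
#' @param reference a [Biostrings::DNAStringSet] from [readReference()].
#' @param threshold minimum depth X, default 1.
#' @return \code{data.frame} of per-taxon rows as in [taxonSummary()].
#' @export
computeTaxonStats <- function(alignments, reads, reference, threshold = 1) {
  mapped <- alignments[alignments$taxon_id != "*", , drop = FALSE]
  lens <- setNames(Biostrings::width(reads), names(reads))
  rows <- lapply(names(reference), function(tx) {
    sub <- mapped[mapped$taxon_id == tx, , drop = FALSE]
    depth <- depthProfile(sub, Biostrings::width(reference)[[match(tx, names(reference))]])
    rl <- lens[sub$read_id]
    rl[is.na(rl)] <- sub$read_length[is.na(rl)]
    taxonSummary(depth, rl[!is.na(rl)], tx,
                 Biostrings::width(reference)[[match(tx, names(reference))]],
                 threshold)
  })
  out <- do.call(rbind, c(rows, list(unmappedStatsRow())))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

unmappedStatsRow <- function() {
  data.frame(taxon_id = "*", taxon_length = 0, taxon_mean_coverage = 0,
             taxon_covered_bases_X = 0, taxon_pct_covered_bases_X = 0,
             total_taxon_ref_mapped_bases = 0, taxon_mean_read_length = 0,
             stringsAsFactors = FALSE)
}

#' Build the per-read sample manifest
#'
#' One row per read id and sequencing-summary occurrence, joining FASTQ,
#' QC, alignment and pore-level fields. When no summary is supplied the
#' pore columns are empty and \code{read_qscore} falls back to
#' [meanQscore()]. \code{is_uniq} is FALSE for read ids occurring in more
#' than one summary row (a strand may be re-evaluated several times before
#' a final decision); \code{end_time = start_time + duration}.
#'
#' @param reads the validated read set.
#' @param qcStatus named logical from [qcFilter()].
#' @param alignments primary records from [selectPrimary()].
#' @param summary optional data.frame from [readSequencingSummary()].
#' @param sampleId sample label for the first column.
#' @return \code{data.frame} with columns \code{sample_id}, \code{read_id},
#'   \code{read_len}, \code{read_qscore}, \code{channel},
#'   \code{start_time}, \code{end_time}, \code{decision},
#'   \code{fastp_status}, \code{is_mapped}, \code{is_uniq},
#'   \code{contig_id}.
#' @export
buildManifest <- function(reads, qcStatus, alignments, summary = NULL,
                          sampleId = "sample") {
  ids <- names(reads)
  lens <- Biostrings::width(reads)
  mapped <- alignments[alignments$taxon_id != "*", , drop = FALSE]
  contig <- setNames(mapped$taxon_id, mapped$read_id)
  status <- unname(qcStatus[ids])
  status[is.na(status)] <- FALSE

  if (!is.null(summary) && nrow(summary)) {
    occ <- table(summary$read_id)
    sumSub <- summary[summary$read_id %in% ids, , drop = FALSE]
    hit <- match(ids, summary$read_id)          # reads with no summary row
    noRow <- ids[is.na(hit)]
    base <- data.frame(
      read_id = c(sumSub$read_id, noRow),
      channel = c(sumSub$channel, rep(NA_integer_, length(noRow))),
      start_time = c(sumSub$start_time, rep(NA_real_, length(noRow))),
      end_time = c(sumSub$start_time + sumSub$duration,
                   rep(NA_real_, length(noRow))),
      decision = c(sumSub$end_reason, rep("", length(noRow))),
      qscore = c(sumSub$mean_qscore_template, rep(NA_real_, length(noRow))),
      stringsAsFactors = FALSE)
    isUniq <- setNames(as.vector(occ) == 1L, names(occ))
    base$is_uniq <- isUniq[base$read_id]
    base$is_uniq[is.na(base$is_uniq)] <- TRUE
    nMissing <- length(noRow)
    if (nMissing) {
      message(nMissing,
              " read(s) had no sequencing-summary row; pore fields left empty")
    }
  } else {
    base <- data.frame(read_id = ids, channel = NA_integer_,
                       start_time = NA_real_, end_time = NA_real_,
                       decision = "", qscore = NA_real_, is_uniq = TRUE,
                       stringsAsFactors = FALSE)
  }
  i <- match(base$read_id, ids)
  base$qscore[is.na(base$qscore)] <-
    if (any(is.na(base$qscore))) meanQscore(reads[i[is.na(base$qscore)]])
    else numeric(0)
  out <- data.frame(
    sample_id = sampleId,
    read_id = base$read_id,
    read_len = lens[i],
    read_qscore = base$qscore,
    channel = base$channel,
    start_time = base$start_time,
    end_time = base$end_time,
    decision = base$decision,
    fastp_status = status[i],
    is_mapped = status[i] & base$read_id %in% names(contig),
    is_uniq = base$is_uniq,
    contig_id = ifelse(status[i] & base$read_id %in% names(contig),
                       unname(contig[base$read_id]), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the sample manifest summary
#'
#' Joins the per-taxon coverage statistics with the sample-wide QC and
#' sketch estimates into the analyze stage's aggregated output: rows
#' ordered by taxon id with the \code{"*"} unmapped row last, and five
#' sample-wide columns attached (\code{est_genome_size},
#' \code{est_coverage}, \code{total_bases}, \code{total_fastp_bases},
#' \code{mean_read_length}).
#'
#' @param taxonStats data.frame from [computeTaxonStats()].
#' @param qcStats \code{stats} element of [qcFilter()].
#' @param sketchEst list with \code{genome_size} and \code{coverage}
#'   (NA allowed when the sketch stage was skipped).
#' @return \code{data.frame}, one row per taxon plus the \code{"*"} row.
#' @export
buildManifestSummary <- function(taxonStats, qcStats,
                                 sketchEst = list(genome_size = NA_real_,
                                                  coverage = NA_real_)) {
  star <- taxonStats$taxon_id == "*"
  body <- taxonStats[!star, , drop = FALSE]
  body <- body[order(body$taxon_id), , drop = FALSE]
  out <- rbind(body, taxonStats[star, , drop = FALSE])
  out$est_genome_size <- sketchEst$genome_size
  out$est_coverage <- sketchEst$coverage
  out$total_bases <- qcStats$total_bases
  out$total_fastp_bases <- qcStats$total_fastp_bases
  out$mean_read_length <- qcStats$mean_read_length
  rownames(out) <- NULL
  attr(out, "threshold") <- attr(taxonStats, "threshold") %||% 1
  out
}

# column headers carry the active breadth threshold, e.g.
# taxon_covered_bases_5X when --minimum_coverage 5
thresholdColname <- function(prefix, threshold) {
  sub("_X$", paste0("_", format(threshold), "X"), prefix)
}

#' Write the sample manifest TSV
#'
#' @param manifest data.frame from [buildManifest()].
#' @param path output path (\code{sample_manifest.txt}).
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  out <- manifest
  for (col in c("fastp_status", "is_mapped", "is_uniq")) {
    out[[col]] <- ifelse(out[[col]], "True", "False")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sample manifest summary TSV
#'
#' Values are written at full precision; presentation rounding (two
#' significant digits for depth and breadth, integer mean read length)
#' belongs to the report stage.
#'
#' @param summary data.frame from [buildManifestSummary()].
#' @param path output path (\code{sample_manifest_summary.txt}).
#' @param threshold breadth threshold used (names the two breadth
#'   columns); defaults to the attribute recorded on \code{summary}.
#' @return \code{path}, invisibly.
#' @export
writeManifestSummary <- function(summary, path,
                                 threshold = attr(summary, "threshold") %||% 1) {
  out <- summary
  colnames(out)[colnames(out) == "taxon_covered_bases_X"] <-
    thresholdColname("taxon_covered_bases_X", threshold)
  colnames(out)[colnames(out) == "taxon_pct_covered_bases_X"] <-
    thresholdColname("taxon_%_covered_bases_X", threshold)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest summary written by [writeManifestSummary()]
#' @param path the TSV path.
#' @return \code{data.frame} with canonical \code{_X} column names and a
#'   \code{"threshold"} attribute.
#' @export
readManifestSummary <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pctCol <- grep("^taxon_%_covered_bases_", colnames(df), value = TRUE)
  thr <- as.numeric(sub("^taxon_%_covered_bases_(.*)X$", "\\1", pctCol))
  colnames(df)[colnames(df) == pctCol] <- "taxon_pct_covered_bases_X"
  covCol <- grep("^taxon_covered_bases_", colnames(df), value = TRUE)
  colnames(df)[colnames(df) == covCol] <- "taxon_covered_bases_X"
  df$taxon_id <- as.character(df$taxon_id)
  attr(df, "threshold") <- thr
  df
}

#' Read a sample manifest written by [writeManifest()]
#' @param path the TSV path.
#' @return \code{data.frame} with logical status columns restored.
#' @export
readManifest <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  for (col in c("fastp_status", "is_mapped", "is_uniq")) {
    df[[col]] <- df[[col]] == "True"
  }
  df$decision <- ifelse(is.na(df$decision), "", df$decision)
  df$contig_id <- ifelse(is.na(df$contig_id), "", df$contig_id)
  df
}
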
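#' Run the analyze stage
#'
#' The core stage of the pipeline: validates the FASTQ (aborting on the
#' first malformed record, before anything is written), applies the QC
#' filter, maps the surviving reads to the reference (external aligner, or
#' a supplied SAM restricted to QC-passed reads), sketches the raw reads
#' for reference-free genome-size/coverage estimates, and writes the two
#' key outputs -- \code{sample_manifest.txt} (per read) and
#' \code{sample_manifest_summary.txt} (per taxon) -- alongside the
#' filtered and mapped-read FASTQs, the alignment SAM, a sketch report
#' and a log.
#'
#' @param fastq input FASTQ path (plain or gzip).
#' @param reference multi-sequence reference FASTA path.
#' @param outDir output directory (created).
#' @param summary optional sequencing-summary TSV path; enables the
#'   pore-level manifest columns (channel, times, decision).
#' @param sam optional alignment SAM/BAM path; when given the external
#'   aligner is not invoked.
#' @param minimumCoverage breadth threshold X (default 1); the summary's
#'   breadth columns are named for it, e.g.
#'   \code{taxon_\%_covered_bases_5X}.
#' @param sequencingMode \code{"long_single"} (default) or
#'   \code{"short_paired"}; selects the aligner preset.
#' @param aligner an [AlignerConfig-class]; ignored when \code{sam} is
#'   supplied.
#' @param qc a [QcParams-class].
#' @param sketchK,sketchS,sketchM,sketchSeed sketch parameters (k-mer
#'   size 27, sketch size 1000, copy threshold 2).
#' @param sampleId sample label used in the manifest.
#' @return (invisibly) list with the output paths plus the in-memory
#'   \code{manifest}, \code{summary} (manifest summary),
#'   \code{taxonStats}, \code{qcStats} and \code{sketch}.
#' @export
runAnalyze <- function(fastq, reference, outDir, summary = NULL, sam = NULL,
                       minimumCoverage = 1,
                       sequencingMode = c("long_single", "short_paired"),
                       aligner = NULL, qc = qcParams(),
                       sketchK = 27, sketchS = 1000, sketchM = 2,
                       sketchSeed = 42, sampleId = "sample") {
  sequencingMode <- match.arg(sequencingMode)
  if (!file.exists(reference)) {
    stop("reference FASTA not found: ", reference, call. = FALSE)
  }
  if (minimumCoverage < 1) {
    stop("minimumCoverage must be >= 1", call. = FALSE)
  }
  # validation gate: all inputs are parsed strictly BEFORE any output is
  # written, so a corrupt record never leaves a partial summary behind
  reads <- readFastq(fastq, strict = TRUE)
  ref <- readReference(reference)
  summaryTab <- if (!is.null(summary)) readSequencingSummary(summary)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "analyze.log")
  cat("", file = logFile)
  psLog("analyze: ", length(reads), " reads, ", length(ref),
        " reference sequences; minimumCoverage=", minimumCoverage,
        "; mode=", sequencingMode, file = logFile)
  sums <- tools::md5sum(c(fastq, reference))
  psLog("input md5: ", paste(names(sums), unname(sums), collapse = "; "),
        file = logFile)

  qcRes <- qcFilter(reads, qc)
  psLog("qc: kept ", qcRes$stats$reads_out, "/", qcRes$stats$reads_in,
        " reads (", qcRes$stats$failures, " failed, ",
        qcRes$stats$duplicates_removed, " duplicates)", file = logFile)
  filteredFastq <- file.path(outDir, "filtered.fastq")
  writeFastq(qcRes$kept, filteredFastq)

  if (is.null(sam)) {
    if (is.null(aligner)) {
      aligner <- alignerConfig(
        preset = if (sequencingMode == "short_paired") "short_read_paired"
                 else "long_read_ont")
    }
    samPath <- file.path(outDir, "alignments.sam")
    alignReads(filteredFastq, reference, samPath, aligner)
    psLog("aligned with ", aligner@executable, " preset ", aligner@preset,
          " -k ", aligner@kmer, file = logFile)
  } else {
    samPath <- sam
    psLog("alignments supplied: ", sam, file = logFile)
  }
  aln <- readSamRecords(samPath)
  seqlen <- attr(aln, "seqlengths")
  known <- names(seqlen) %in% names(ref)
  if (length(seqlen) && !all(known)) {
    stop("alignment targets absent from the reference FASTA: ",
         paste(names(seqlen)[!known], collapse = ", "), call. = FALSE)
  }
  # only reads of this condition's FASTQ count, and QC-failed reads are
  # never counted as mapped (a supplied SAM may span the whole flow cell)
  nForeign <- sum(!(aln$read_id %in% names(reads)))
  if (nForeign) {
    psLog("dropped ", nForeign, " alignment record(s) for reads outside ",
          "the input FASTQ", file = logFile)
  }
  aln <- aln[aln$read_id %in% names(qcRes$kept), , drop = FALSE]
  primary <- selectPrimary(aln)

  sketch <- tryCatch(
    sketchReads(reads, k = sketchK, s = sketchS, m = sketchM,
                seed = sketchSeed),
    error = function(e) {
      psLog("sketch skipped: ", conditionMessage(e), file = logFile)
      NULL
    })
  sketchEst <- if (is.null(sketch)) {
    list(genome_size = NA_real_, coverage = NA_real_)
  } else {
    list(genome_size = estimateGenomeSize(sketch),
         coverage = estimateCoverage(sketch))
  }

  taxonStats <- computeTaxonStats(primary, reads, ref,
                                  threshold = minimumCoverage)
  manifest <- buildManifest(reads, qcRes$status, primary, summaryTab,
                            sampleId = sampleId)
  manifestSummary <- buildManifestSummary(taxonStats, qcRes$stats, sketchEst)

  manifestPath <- file.path(outDir, "sample_manifest.txt")
  summaryPath <- file.path(outDir, "sample_manifest_summary.txt")
  writeManifest(manifest, manifestPath)
  writeManifestSummary(manifestSummary, summaryPath,
                       threshold = minimumCoverage)

  mappedIds <- primary$read_id[primary$taxon_id != "*"]
  mappedFastq <- file.path(outDir, "mapped_reads.fastq")
  writeFastq(reads[names(reads) %in% mappedIds], mappedFastq)

  sketchReport <- file.path(outDir, "sketch.json")
  jsonlite::write_json(
    list(k = sketchK, s = sketchS, m = sketchM,
         n_hashes = if (is.null(sketch)) 0L else length(sketch@hashes),
         est_genome_size = sketchEst$genome_size,
         est_coverage = sketchEst$coverage),
    sketchReport, auto_unbox = TRUE, digits = NA, na = "null")
  psLog("est_genome_size=", format(sketchEst$genome_size),
        " est_coverage=", format(sketchEst$coverage), file = logFile)
  psLog("wrote ", manifestPath, " and ", summaryPath, file = logFile)

  invisible(list(outDir = outDir, manifest_path = manifestPath,
                 summary_path = summaryPath, filtered_fastq = filteredFastq,
                 mapped_fastq = mappedFastq, sam = samPath,
                 sketch_report = sketchReport, log = logFile,
                 manifest = manifest, summary = manifestSummary,
                 taxonStats = taxonStats, qcStats = qcRes$stats,
                 sketch = sketch))
}

#' Run the full test-vs-control pipeline
#'
#' Runs the analyze stage once per condition and then the report stage on
#' the two output directories, mirroring how an AS flow cell split into
#' test and control channel halves is evaluated.
#'
#' @param testArgs,controlArgs named lists of arguments for
#'   [runAnalyze()] (\code{outDir} defaults to \code{test}/\code{control}
#'   under \code{reportDir}'s parent if missing).
#' @param reportDir output directory for the comparative report.
#' @param AS render the decision charts (requires sequencing summaries in
#'   both analyze runs).
#' @param binMinutes decision bin width in minutes, default 15.
#' @return (invisibly) list with \code{test}, \code{control} (analyze
#'   results) and \code{report} (files written).
#' @export
runPipelinePair <- function(testArgs, controlArgs, reportDir, AS = FALSE,
                            binMinutes = 15) {
  testArgs$sampleId <- testArgs$sampleId %||% "test"
  controlArgs$sampleId <- controlArgs$sampleId %||% "control"
  test <- tryCatch(do.call(runAnalyze, testArgs),
                   error = function(e) stop("analyze (test) failed: ",
                                            conditionMessage(e), call. = FALSE))
  control <- tryCatch(do.call(runAnalyze, controlArgs),
                      error = function(e) stop("analyze (control) failed: ",
                                               conditionMessage(e), call. = FALSE))
  report <- tryCatch(
    renderReports(test$outDir, control$outDir, reportDir, AS = AS,
                  binMinutes = binMinutes),
    error = function(e) stop("plot failed: ", conditionMessage(e),
                             call. = FALSE))
  invisible(list(test = test, control = control, report = report))
}
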
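#' @title A mock adaptive-sampling run scenario
#'
#' @description Defines a complete synthetic AS experiment: a mock
#' community of independent random genomes with fixed relative
#' abundances, a channel layout with an AS (depleting) subrange, a
#' depletion target and a planted unblock rate. The defaults emulate a
#' log-distributed mock community dominated by the depletion target
#' sequenced on a 512-channel flow cell with AS on channels 1-256:
#' target-taxon strands on AS channels are ejected after roughly 400
#' bases (a ~1 s decision window at 400 b/s) and annotated
#' \code{data_service_unblock_mux_change}, while everything else ends
#' \code{signal_positive} except a small fraction of undecided events
#' (\code{signal_negative} / \code{unblock_mux_change}).
#'
#' @slot taxa data.frame with \code{taxon_id}, \code{genome_length},
#'   \code{abundance} (abundances sum to 1).
#' @slot readCount total reads to simulate.
#' @slot readLengthMeanlog,readLengthSdlog log-normal read-length
#'   parameters.
#' @slot errorRate per-base substitution rate.
#' @slot channels inclusive channel range \code{c(min, max)}.
#' @slot asChannels subrange performing AS depletion.
#' @slot depletionTarget taxon id being depleted.
#' @slot unblockRate planted fraction of AS-channel pore events ending
#'   unblocked (realised by unblocking target reads with probability
#'   \code{unblockRate / target abundance}).
#' @slot noDecisionRate fraction of non-unblocked events annotated
#'   signal_negative / unblock_mux_change.
#' @slot reevalFraction fraction of reads given an extra
#'   (signal_negative) summary row, emulating strand re-evaluation.
#' @slot truncationLength mean truncated length of unblocked reads
#'   (bases).
#' @slot runDuration run length in seconds.
#' @slot seed integer; fixes every random choice, so equal seeds give
#'   byte-identical output files.
#' @export
setClass("RunScenario", representation(
  taxa = "data.frame", readCount = "integer",
  readLengthMeanlog = "numeric", readLengthSdlog = "numeric",
  errorRate = "numeric", channels = "integer", asChannels = "integer",
  depletionTarget = "character", unblockRate = "numeric",
  noDecisionRate = "numeric", reevalFraction = "numeric",
  truncationLength = "numeric", runDuration = "numeric", seed = "numeric"))

setValidity("RunScenario", function(object) {
  tx <- object@taxa
  if (!all(c("taxon_id", "genome_length", "abundance") %in% colnames(tx))) {
    return("taxa needs columns taxon_id, genome_length, abundance")
  }
  if (abs(sum(tx$abundance) - 1) > 1e-9) {
    return(paste0("relative abundances must sum to 1 (got ",
                  sum(tx$abundance), ")"))
  }
  if (!object@depletionTarget %in% tx$taxon_id) {
    return("depletionTarget is not one of the taxa")
  }
  if (object@asChannels[1] < object@channels[1] ||
      object@asChannels[2] > object@channels[2]) {
    return("asChannels must lie within channels")
  }
  targetAb <- tx$abundance[tx$taxon_id == object@depletionTarget]
  if (object@unblockRate > targetAb + 1e-9) {
    return("unblockRate cannot exceed the depletion target's abundance")
  }
  TRUE
})

#' Build a run scenario
#'
#' @param taxa data.frame (\code{taxon_id}, \code{genome_length},
#'   \code{abundance}); the default is a four-taxon log-distributed mock
#'   community with the depletion target at 80\% abundance.
#' @param readCount,readLengthMeanlog,readLengthSdlog,errorRate,channels,asChannels,depletionTarget,unblockRate,noDecisionRate,reevalFraction,truncationLength,runDuration,seed
#'   see [RunScenario-class].
#' @return a validated [RunScenario-class] object.
#' @export
runScenario <- function(
    taxa = data.frame(
      taxon_id = c("Mock_target", "Mock_commensal_A",
                   "Mock_commensal_B", "Mock_rare"),
      genome_length = c(60000L, 40000L, 30000L, 20000L),
      abundance = c(0.80, 0.10, 0.06, 0.04)),
    readCount = 6000, readLengthMeanlog = log(2000), readLengthSdlog = 0.6,
    errorRate = 0.02, channels = c(1L, 512L), asChannels = c(1L, 256L),
    depletionTarget = "Mock_target", unblockRate = 0.60,
    noDecisionRate = 0.05, reevalFraction = 0.02,
    truncationLength = 400, runDuration = 7200, seed = 7) {
  new("RunScenario", taxa = taxa, readCount = as.integer(readCount),
      readLengthMeanlog = readLengthMeanlog, readLengthSdlog = readLengthSdlog,
      errorRate = errorRate, channels = as.integer(channels),
      asChannels = as.integer(asChannels),
      depletionTarget = depletionTarget, unblockRate = unblockRate,
      noDecisionRate = noDecisionRate, reevalFraction = reevalFraction,
      truncationLength = truncationLength, runDuration = runDuration,
      seed = seed)
}

setMethod("show", "RunScenario", function(object) {
  cat("RunScenario:", object@readCount, "reads over",
      nrow(object@taxa), "taxa; AS channels",
      paste(object@asChannels, collapse = "-"), "depleting",
      object@depletionTarget, "at planted unblock rate",
      object@unblockRate, "\n")
})

randomGenome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutateReads <- function(seqs, errorRate) {
  if (errorRate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, errorRate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1L]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

qualityStrings <- function(lens, meanQ) {
  vapply(seq_along(lens), function(i) {
    q <- round(rnorm(lens[i], meanQ[i], 3))
    q[q < 2] <- 2L; q[q > 40] <- 40L
    rawToChar(as.raw(q + 33L))
  }, character(1))
}

#' Generate a complete synthetic AS run
#'
#' Writes four mutually consistent files -- \code{reference.fasta},
#' \code{reads.fastq}, \code{sequencing_summary.txt} and
#' \code{truth.sam} (the generating coordinates of every read) -- plus
#' \code{truth.json} recording the scenario parameters and planted truth.
#' Reads are substrings of their source genome with i.i.d. substitution
#' errors; unblocked reads are truncated to about the scenario's
#' truncation length; summary rows agree with the FASTQ (lengths, mean Q)
#' and carry the planted end reasons. Genomes are independent uniform
#' random sequences, so mapping truth is unambiguous. All randomness
#' flows from the scenario seed: equal seeds give byte-identical files.
#'
#' @param scenario a [RunScenario-class] object.
#' @param outDir output directory (created).
#' @return (invisibly) list with the four file paths, \code{truth_json},
#'   and the in-memory \code{reference}, \code{reads}, \code{summary} and
#'   truth data.frame \code{truth}.
#' @export
generateRun <- function(scenario, outDir) {
  validObject(scenario)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  withSeed(scenario@seed, {
    tx <- scenario@taxa
    genomes <- setNames(vapply(tx$genome_length, randomGenome, character(1)),
                        tx$taxon_id)
    n <- scenario@readCount
    ids <- sprintf("simread_%06d", seq_len(n))
    taxon <- sample(tx$taxon_id, n, replace = TRUE, prob = tx$abundance)
    glen <- setNames(tx$genome_length, tx$taxon_id)[taxon]
    fullLen <- pmin(pmax(round(rlnorm(n, scenario@readLengthMeanlog,
                                      scenario@readLengthSdlog)), 100L),
                    glen - 1L)
    start <- floor(runif(n, 1, glen - fullLen + 1))
    channel <- sample(seq(scenario@channels[1], scenario@channels[2]), n,
                      replace = TRUE)

    onAS <- channel >= scenario@asChannels[1] & channel <= scenario@asChannels[2]
    targetAb <- tx$abundance[tx$taxon_id == scenario@depletionTarget]
    unblockProb <- scenario@unblockRate / targetAb
    unblocked <- onAS & taxon == scenario@depletionTarget &
      runif(n) < unblockProb
    truncLen <- pmax(round(rnorm(n, scenario@truncationLength,
                                 scenario@truncationLength * 0.1)), 50L)
    len <- ifelse(unblocked, pmin(fullLen, truncLen), fullLen)

    endReason <- rep("signal_positive", n)
    endReason[unblocked] <- "data_service_unblock_mux_change"
    nd <- !unblocked & runif(n) < scenario@noDecisionRate
    endReason[nd] <- sample(c("signal_negative", "unblock_mux_change"),
                            sum(nd), replace = TRUE)

    seqs <- substring(genomes[taxon], start, start + len - 1L)
    seqs <- mutateReads(seqs, scenario@errorRate)
    meanQ <- pmin(pmax(rnorm(n, 19, 2.5), 7), 35)
    quals <- qualityStrings(len, meanQ)
    reads <- newFastqSet(ids, seqs, quals,
                         desc = paste0(ids, " ch=", channel))

    duration <- len / 400                       # 400 b/s sequencing speed
    startTime <- round(runif(n, 0, pmax(scenario@runDuration - duration, 0)), 2)
    summary <- data.frame(
      read_id = ids, channel = channel, start_time = startTime,
      duration = round(duration, 2), sequence_length_template = len,
      mean_qscore_template = round(meanQscore(reads), 2),
      end_reason = endReason, stringsAsFactors = FALSE)

    # strand re-evaluation: an extra short signal_negative event per read
    nRe <- floor(scenario@reevalFraction * n)
    if (nRe > 0) {
      reIdx <- sample.int(n, nRe)
      extra <- summary[reIdx, , drop = FALSE]
      extra$start_time <- pmax(extra$start_time - 2, 0)
      extra$duration <- 0.5
      extra$sequence_length_template <- 200
      extra$end_reason <- "signal_negative"
      summary <- rbind(summary, extra)
      summary <- summary[order(match(summary$read_id, ids),
                               summary$start_time), , drop = FALSE]
      rownames(summary) <- NULL
    }

    paths <- list(
      reference = file.path(outDir, "reference.fasta"),
      fastq = file.path(outDir, "reads.fastq"),
      summary = file.path(outDir, "sequencing_summary.txt"),
      sam = file.path(outDir, "truth.sam"),
      truth_json = file.path(outDir, "truth.json"))

    ref <- Biostrings::DNAStringSet(genomes)
    Biostrings::writeXStringSet(ref, paths$reference)
    writeFastq(reads, paths$fastq)
    writeSequencingSummary(summary, paths$summary)

    samHeader <- c("@HD\tVN:1.6\tSO:unknown",
                   sprintf("@SQ\tSN:%s\tLN:%d", tx$taxon_id, tx$genome_length))
    samBody <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       ids, taxon, start, len)
    writeLines(c(samHeader, samBody), paths$sam)

    truth <- data.frame(read_id = ids, taxon_id = taxon, start = start,
                        length = len, full_length = fullLen,
                        channel = channel, unblocked = unblocked,
                        end_reason = endReason, stringsAsFactors = FALSE)
    jsonlite::write_json(
      list(taxa = tx, read_count = n, error_rate = scenario@errorRate,
           depletion_target = scenario@depletionTarget,
           planted_unblock_rate = scenario@unblockRate,
           as_channels = scenario@asChannels,
           channels = scenario@channels,
           n_unblocked = sum(unblocked), seed = scenario@seed),
      paths$truth_json, auto_unbox = TRUE, digits = NA)

    invisible(c(paths, list(referenceSet = ref, reads = reads,
                            summaryTable = summary, truth = truth)))
  })
}
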
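# the five comparative parameters, in the order they are reported
# ('%' sorts before letters, matching alphabetical order of the labels)
summaryParameters <- function(threshold) {
  c(thresholdColname("taxon_%_covered_bases_X", threshold),
    thresholdColname("taxon_covered_bases_X", threshold),
    "taxon_mean_coverage",
    "taxon_mean_read_length",
    "total_taxon_ref_mapped_bases")
}

#' Build the test-vs-control summary table
#'
#' Five rows per taxon (breadth percent, covered bases, mean coverage,
#' mean read length, total mapped bases), taxa in manifest-summary order
#' with the unmapped \code{"*"} row last. Values are full precision;
#' rendering rounds mean coverage to two decimals and the rest to the
#' nearest integer.
#'
#' @param test,control manifest summaries ([buildManifestSummary()] /
#'   [readManifestSummary()]) sharing one reference set.
#' @return data.frame with \code{taxon_id}, \code{parameter},
#'   \code{test_value}, \code{control_value}.
#' @export
buildSummaryTable <- function(test, control) {
  if (!setequal(test$taxon_id, control$taxon_id)) {
    onlyT <- setdiff(test$taxon_id, control$taxon_id)
    onlyC <- setdiff(control$taxon_id, test$taxon_id)
    stop("test and control were produced against different reference sets; ",
         if (length(onlyT)) paste0("only in test: ",
                                   paste(onlyT, collapse = ", "), "; "),
         if (length(onlyC)) paste0("only in control: ",
                                   paste(onlyC, collapse = ", ")),
         call. = FALSE)
  }
  thr <- attr(test, "threshold") %||% 1
  params <- summaryParameters(thr)
  cols <- c("taxon_pct_covered_bases_X", "taxon_covered_bases_X",
            "taxon_mean_coverage", "taxon_mean_read_length",
            "total_taxon_ref_mapped_bases")
  ctrl <- control[match(test$taxon_id, control$taxon_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(test)), function(i) {
    data.frame(taxon_id = test$taxon_id[i], parameter = params,
               test_value = as.numeric(test[i, cols]),
               control_value = as.numeric(ctrl[i, cols]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Table-style rounding for rendered outputs: mean coverage to two
# decimals, everything else to the nearest integer
renderSummaryValues <- function(tab) {
  isCov <- tab$parameter == "taxon_mean_coverage"
  tab$test_value <- ifelse(isCov, round(tab$test_value, 2),
                           round0(tab$test_value))
  tab$control_value <- ifelse(isCov, round(tab$control_value, 2),
                              round0(tab$control_value))
  tab
}

# read an analyze output directory (the --test_dir / --control_dir unit)
readAnalyzeDir <- function(dir) {
  man <- file.path(dir, "sample_manifest.txt")
  summ <- file.path(dir, "sample_manifest_summary.txt")
  if (!file.exists(man) || !file.exists(summ)) {
    stop("not an analyze output directory (missing sample_manifest.txt or ",
         "sample_manifest_summary.txt): ", dir, call. = FALSE)
  }
  list(manifest = readManifest(man), summary = readManifestSummary(summ))
}

#' Render the comparative report
#'
#' The report stage: compares two analyze output directories and writes
#' the five default charts (read-length violin, Q-score violin, mean
#' read-length bars, mean-coverage bars with a linear/log y-axis toggle,
#' percent-covered bars), the rendered \code{summary_table.csv}, and --
#' when \code{AS = TRUE} -- the independent and cumulative time-binned
#' decision charts. Every chart is backed by a plain CSV of its plotted
#' values so results are testable without a browser; HTML files embed the
#' figures as self-contained images.
#'
#' @param testDir,controlDir analyze output directories.
#' @param outputDir report directory (created).
#' @param AS also render the two decision charts (requires pore-level
#'   decision data in the manifests).
#' @param binMinutes decision bin width in minutes, default 15.
#' @param maxViolinReads violin charts downsample to this many reads per
#'   condition (fixed seed) to bound rendering cost; default 100000.
#' @param seed seed for the violin downsampling.
#' @return (invisibly) character vector of files written.
#' @export
renderReports <- function(testDir, controlDir, outputDir, AS = FALSE,
                          binMinutes = 15, maxViolinReads = 100000,
                          seed = 1) {
  test <- readAnalyzeDir(testDir)
  control <- readAnalyzeDir(controlDir)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(p) { written <<- c(written, p); p }

  # summary table (rendered rounding applied here, and only here)
  tab <- renderSummaryValues(buildSummaryTable(test$summary, control$summary))
  write.csv(tab, emit(file.path(outputDir, "summary_table.csv")),
            row.names = FALSE, quote = FALSE)

  both <- rbind(cbind(condition = "test", test$manifest),
                cbind(condition = "control", control$manifest))

  # violins: read length and Q score
  violin <- both[, c("condition", "read_id", "read_len", "read_qscore")]
  violin <- violin[!duplicated(paste(violin$condition, violin$read_id)), ]
  violin <- downsampleByCondition(violin, maxViolinReads, seed)
  writeChart(outputDir, "read_length_violin", violin,
             violinPlot(violin, "read_len", "Read length (bases)"), emit)
  writeChart(outputDir, "read_qscore_violin", violin,
             violinPlot(violin, "read_qscore", "Mean Q score"), emit)

  # per-taxon bars (taxon rows only; the "*" row carries no coverage)
  thr <- attr(test$summary, "threshold") %||% 1
  bars <- rbind(cbind(condition = "test", test$summary),
                cbind(condition = "control", control$summary))
  bars <- bars[bars$taxon_id != "*", ]
  writeChart(outputDir, "mean_read_length_bar",
             bars[, c("condition", "taxon_id", "taxon_mean_read_length")],
             barPlot(bars, "taxon_mean_read_length", "Mean read length (bases)"),
             emit)
  writeChart(outputDir, "pct_covered_bar",
             bars[, c("condition", "taxon_id", "taxon_pct_covered_bases_X")],
             barPlot(bars, "taxon_pct_covered_bases_X",
                     sprintf("%% bases covered at %sX", format(thr))), emit)
  covCsv <- bars[, c("condition", "taxon_id", "taxon_mean_coverage")]
  covLinear <- barPlot(bars, "taxon_mean_coverage", "Mean coverage depth")
  covLog <- covLinear + ggplot2::scale_y_log10()
  writeChart(outputDir, "mean_coverage_bar", covCsv,
             list(linear = covLinear, log = covLog), emit)

  if (AS) {
    hasDecisions <- function(m) any(nzchar(m$decision))
    if (!hasDecisions(test$manifest) && !hasDecisions(control$manifest)) {
      stop("AS report requested but the manifests carry no end_reason ",
           "decision data (was analyze run with a sequencing summary?)",
           call. = FALSE)
    }
    w <- binMinutes * 60
    indep <- rbind(cbind(condition = "test",
                         binDecisions(test$manifest, w)),
                   cbind(condition = "control",
                         binDecisions(control$manifest, w)))
    cum <- rbind(cbind(condition = "test",
                       cumulateBins(binDecisions(test$manifest, w))),
                 cbind(condition = "control",
                       cumulateBins(binDecisions(control$manifest, w))))
    writeChart(outputDir, "decision_independent", indep,
               decisionPlot(indep, "Independent decision bins"), emit)
    writeChart(outputDir, "decision_cumulative", cum,
               decisionPlot(cum, "Cumulative decision bins"), emit)
  }
  invisible(written)
}

downsampleByCondition <- function(df, maxRows, seed) {
  withSeed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$condition), function(i) {
      if (length(i) > maxRows) sort(sample(i, maxRows)) else i
    }), use.names = FALSE)
    df[sort(keep), , drop = FALSE]
  })
}

violinPlot <- function(df, var, ylab) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data[[var]],
                                   fill = .data$condition)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

barPlot <- function(df, var, ylab) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon_id, y = .data[[var]],
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = ylab, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

decisionPlot <- function(bins, title) {
  long <- do.call(rbind, lapply(decisionClasses, function(cl) {
    data.frame(condition = bins$condition, bin_end = bins$bin_end,
               class = cl, pct = bins[[paste0("pct_", cl)]])
  }))
  scale <- max(bins$read_count, 1)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_end / 3600)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pct, fill = .data$class),
                      width = diff(range(long$bin_end / 3600)) /
                        max(length(unique(long$bin_end)), 1) * 0.9) +
    ggplot2::geom_line(data = bins,
                       ggplot2::aes(y = .data$read_count / scale * 100),
                       colour = "black") +
    ggplot2::scale_y_continuous(
      name = "% of sequencing decisions",
      sec.axis = ggplot2::sec_axis(~ . * scale / 100, name = "read count")) +
    ggplot2::facet_wrap(~ condition, ncol = 1) +
    ggplot2::labs(x = "Run time (h)", title = title, fill = NULL) +
    ggplot2::theme_minimal()
}

# write <name>.csv always, and <name>.html embedding the figure(s); when
# several figures are given (e.g. linear/log axis configs) the HTML holds
# both with a client-side toggle
writeChart <- function(dir, name, csvData, figs, emit) {
  write.csv(csvData, emit(file.path(dir, paste0(name, ".csv"))),
            row.names = FALSE, quote = FALSE)
  if (methods::is(figs, "ggplot")) figs <- list(figure = figs)
  imgs <- lapply(figs, encodePlot)
  writeChartHtml(emit(file.path(dir, paste0(name, ".html"))), name, imgs)
}

# render a ggplot to PNG and return it base64-encoded (NULL if no
# graphics device is usable in this session; the CSV twin always exists)
encodePlot <- function(p) {
  png <- tempfile(fileext = ".png")
  ok <- tryCatch({
    grDevices::png(png, width = 900, height = 600, res = 110)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) { try(grDevices::dev.off(), silent = TRUE); FALSE })
  if (!ok || !file.exists(png)) return(NULL)
  jsonlite::base64_enc(readBin(png, "raw", file.info(png)$size))
}

writeChartHtml <- function(path, title, imgs) {
  body <- character(0)
  labels <- names(imgs)
  for (i in seq_along(imgs)) {
    shown <- if (i == 1L) "block" else "none"
    body <- c(body, if (is.null(imgs[[i]])) {
      sprintf("<div id='fig%d' style='display:%s'><p>(figure unavailable; see the CSV twin)</p></div>", i, shown)
    } else {
      sprintf("<div id='fig%d' style='display:%s'><img alt='%s' src='data:image/png;base64,%s'/></div>",
              i, shown, labels[i], gsub("\n", "", imgs[[i]]))
    })
  }
  toggle <- if (length(imgs) > 1L) {
    btns <- sprintf(
      "<button onclick=\"%s\">%s</button>",
      vapply(seq_along(imgs), function(i) paste0(
        paste0(sprintf("document.getElementById('fig%d').style.display='none';",
                       seq_along(imgs)), collapse = ""),
        sprintf("document.getElementById('fig%d').style.display='block';", i)),
        character(1)),
      labels)
    paste0("<p>Y axis: ", paste(btns, collapse = " "), "</p>")
  } else ""
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'/>",
            sprintf("<title>%s</title></head><body>", title),
            sprintf("<h1>%s</h1>", title), toggle, body,
            sprintf("<p>Data: <a href='%s.csv'>%s.csv</a></p>", title, title),
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}
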
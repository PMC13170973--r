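test_that("summary table has five rows per taxon in rendering order", {
  fx <- smallRunFixture()
  tab <- buildSummaryTable(fx$test$summary, fx$control$summary)
  taxa <- unique(tab$taxon_id)
  expect_identical(nrow(tab), 5L * length(taxa))
  expect_identical(taxa[length(taxa)], "*")          # unmapped row last
  params <- tab$parameter[tab$taxon_id == taxa[1]]
  expect_identical(params, sort(params))             # alphabetical parameters
  expect_identical(params[1], "taxon_%_covered_bases_1X")
})

test_that("identical inputs give equal test and control values", {
  fx <- smallRunFixture()
  tab <- buildSummaryTable(fx$test$summary, fx$test$summary)
  expect_equal(tab$test_value, tab$control_value)
})

test_that("mismatched taxon sets are an error listing the difference", {
  fx <- smallRunFixture()
  chopped <- fx$control$summary[fx$control$summary$taxon_id != "Mock_rare", ]
  attr(chopped, "threshold") <- 1
  expect_error(buildSummaryTable(fx$test$summary, chopped), "Mock_rare")
})

test_that("summary table values equal the manifest summaries pre-rounding", {
  fx <- smallRunFixture()
  tab <- buildSummaryTable(fx$test$summary, fx$control$summary)
  for (tx in c("Mock_target", "Mock_rare")) {
    got <- tab$test_value[tab$taxon_id == tx &
                          tab$parameter == "taxon_mean_coverage"]
    want <- fx$test$summary$taxon_mean_coverage[
      fx$test$summary$taxon_id == tx]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # rendering rounds depth to 2 decimals and the rest to integers
  rendered <- poreSight:::renderSummaryValues(tab)
  isCov <- rendered$parameter == "taxon_mean_coverage"
  expect_equal(rendered$test_value[isCov],
               round(tab$test_value[isCov], 2))
  expect_equal(rendered$test_value[!isCov],
               round(tab$test_value[!isCov]))
})

test_that("default report emits five charts with CSV twins and no decision charts", {
  fx <- smallRunFixture()
  out <- file.path(tempdir(), "report-default")
  files <- renderReports(file.path(fx$dir, "test_out"),
                         file.path(fx$dir, "control_out"), out, AS = FALSE)
  base <- basename(files)
  expect_identical(sum(grepl("\\.html$", base)), 5L)
  expect_true(all(c("read_length_violin.csv", "read_qscore_violin.csv",
                    "mean_read_length_bar.csv", "mean_coverage_bar.csv",
                    "pct_covered_bar.csv", "summary_table.csv") %in% base))
  expect_false(any(grepl("decision", base)))
})

test_that("AS report adds the independent and cumulative decision charts", {
  fx <- smallRunFixture()
  out <- file.path(tempdir(), "report-as")
  files <- renderReports(file.path(fx$dir, "test_out"),
                         file.path(fx$dir, "control_out"), out, AS = TRUE)
  base <- basename(files)
  expect_identical(sum(grepl("\\.html$", base)), 7L)
  expect_gte(sum(grepl("\\.csv$", base)), 7L)
  ind <- read.csv(file.path(out, "decision_independent.csv"))
  expect_true(all(c("test", "control") %in% ind$condition))
  # control half of the flow cell never unblocks
  expect_true(all(ind$pct_unblocked[ind$condition == "control"] == 0))
})

test_that("chart-backing CSVs are bit-identical across repeated runs", {
  fx <- smallRunFixture()
  out1 <- file.path(tempdir(), "report-rep1")
  out2 <- file.path(tempdir(), "report-rep2")
  f1 <- renderReports(file.path(fx$dir, "test_out"),
                      file.path(fx$dir, "control_out"), out1, AS = TRUE)
  f2 <- renderReports(file.path(fx$dir, "test_out"),
                      file.path(fx$dir, "control_out"), out2, AS = TRUE)
  csv1 <- sort(f1[grepl("\\.csv$", f1)])
  csv2 <- sort(f2[grepl("\\.csv$", f2)])
  expect_identical(unname(tools::md5sum(csv1)), unname(tools::md5sum(csv2)))
})

test_that("depletion lowers test coverage for the target taxon only", {
  fx <- smallRunFixture()
  out <- file.path(tempdir(), "report-depl")
  renderReports(file.path(fx$dir, "test_out"),
                file.path(fx$dir, "control_out"), out)
  cov <- read.csv(file.path(out, "mean_coverage_bar.csv"))
  wide <- reshape(cov, idvar = "taxon_id", timevar = "condition",
                  direction = "wide")
  tgt <- wide$taxon_id == "Mock_target"
  expect_true(all(wide$taxon_mean_coverage.test[tgt] <
                  wide$taxon_mean_coverage.control[tgt]))
  expect_true(all(wide$taxon_mean_coverage.test[!tgt] >=
                  wide$taxon_mean_coverage.control[!tgt] * 0.5))
})
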
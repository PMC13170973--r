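test_that("end reasons map to the three decision classes", {
  expect_identical(classifyEndReason("signal_positive"), "stop_receiving")
  expect_identical(classifyEndReason("data_service_unblock_mux_change"),
                   "unblocked")
  expect_identical(classifyEndReason("signal_negative"), "no_decision")
  expect_identical(classifyEndReason("unblock_mux_change"), "no_decision")
  # classification is pure and case/whitespace-insensitive
  expect_identical(classifyEndReason(c("Signal_positive", " SIGNAL_POSITIVE ")),
                   rep("stop_receiving", 2))
  expect_identical(classifyEndReason("mux_change"), "unknown")
})

test_that("events land in floor(start/width) bins spanning the run", {
  rows <- data.frame(start_time = c(100, 200, 1000),
                     decision = "signal_positive")
  b <- binDecisions(rows, 900)
  expect_identical(nrow(b), 2L)
  expect_identical(b$read_count, c(2L, 1L))
  expect_identical(b$bin_start, c(0, 900))
  expect_identical(b$bin_end, c(900, 1800))
  expect_true(all(b$pct_stop_receiving == 100))
})

test_that("an all-accept run is 100% stop_receiving in every bin", {
  rows <- data.frame(start_time = runif(200, 0, 5000),
                     decision = "signal_positive")
  b <- binDecisions(rows, 900)
  expect_true(all(b$pct_stop_receiving[b$read_count > 0] == 100))
  expect_true(all(b$pct_unblocked == 0))
})

test_that("planted per-bin percentages are recovered exactly", {
  set.seed(51)
  bin1 <- data.frame(start_time = runif(100, 0, 899),
                     decision = rep(c("data_service_unblock_mux_change",
                                      "signal_positive"), c(60, 40)))
  bin2 <- data.frame(start_time = runif(50, 900, 1799),
                     decision = rep(c("signal_negative", "signal_positive"),
                                    c(10, 40)))
  b <- binDecisions(rbind(bin1, bin2), 900)
  expect_equal(b$pct_unblocked[1], 60)
  expect_equal(b$pct_stop_receiving[1], 40)
  expect_equal(b$pct_no_decision[2], 20)
  expect_identical(b$read_count, c(100L, 50L))
  expect_equal(b$pct_stop_receiving + b$pct_unblocked + b$pct_no_decision,
               rep(100, 2), tolerance = 1e-9)
})

test_that("unknown tokens are excluded from counts and percentages", {
  rows <- data.frame(start_time = c(1, 2, 3, 4),
                     decision = c("signal_positive", "mux_change",
                                  "mux_change", "signal_positive"))
  b <- binDecisions(rows, 10)
  expect_identical(sum(b$read_count), 2L)
  expect_identical(attr(b, "unknown"), 2L)
  expect_equal(b$pct_stop_receiving[1], 100)
  onlyUnknown <- data.frame(start_time = 1, decision = "mux_change")
  expect_identical(nrow(binDecisions(onlyUnknown, 10)), 0L)
})

test_that("cumulative bins aggregate all earlier bins", {
  rows <- data.frame(start_time = c(rep(10, 10), rep(1000, 30)),
                     decision = c(rep("signal_positive", 10),
                                  rep("data_service_unblock_mux_change", 30)))
  indep <- binDecisions(rows, 900)
  cum <- cumulateBins(indep)
  expect_identical(cum$read_count, c(10L, 40L))
  expect_equal(cum$pct_unblocked, c(0, 75))
  one <- binDecisions(rows[1:10, ], 900)
  expect_equal(cumulateBins(one)$pct_stop_receiving,
               one$pct_stop_receiving)            # single bin: identity
})

test_that("the final cumulative bin equals the whole-run tally", {
  set.seed(53)
  rows <- data.frame(
    start_time = runif(800, 0, 7200),
    decision = sample(c("signal_positive", "data_service_unblock_mux_change",
                        "signal_negative", "unblock_mux_change"),
                      800, replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1)))
  indep <- binDecisions(rows, 900)
  expect_identical(sum(indep$read_count), 800L)   # all rows classified once
  cum <- cumulateBins(indep)
  last <- cum[nrow(cum), ]
  cls <- classifyEndReason(rows$decision)
  expect_identical(last$read_count, 800L)
  expect_equal(last$pct_unblocked, 100 * mean(cls == "unblocked"),
               tolerance = 1e-9)
  expect_equal(last$pct_stop_receiving, 100 * mean(cls == "stop_receiving"),
               tolerance = 1e-9)
  expect_equal(last$pct_no_decision, 100 * mean(cls == "no_decision"),
               tolerance = 1e-9)
})
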
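test_that("single detections score by tolerance and case type", {
  expect_identical(score_detection(2.05, 2.00, 0.2), "TP")
  expect_identical(score_detection(2.50, 2.00, 0.2), "FN")
  expect_identical(score_detection(NA, 2.00, 0.2), "FN")
  expect_identical(score_detection(1.3, NA, 0.2), "FP")
  expect_identical(score_detection(NA, NA, 0.2), "TN")
})

test_that("rates, RMSE and advance follow their definitions", {
  # 10 activation cases: 8 within tolerance, 2 outside; 10 negatives: 1 FP
  t_true <- c(rep(2, 10), rep(NA, 10))
  t_hat <- c(rep(2.05, 8), 3.0, 3.0, rep(NA, 9), 1.0)
  r <- summarize_eval(t_hat, t_true, tolerance_s = 0.2)
  expect_identical(c(r$TP, r$FN, r$TN, r$FP), c(8L, 2L, 9L, 1L))
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 0.9)
  expect_equal(r$fnr, 0.2)
  expect_equal(r$fpr, 0.1)

  r2 <- summarize_eval(c(2.1, 1.9), c(2, 2), tolerance_s = 0.2)
  expect_equal(r2$rmse_s, 0.1)

  # a method referenced against itself has zero advance
  r3 <- summarize_eval(c(2.1, 1.9), c(2, 2), t_ref = c(2.1, 1.9))
  expect_identical(r3$advance_s, 0)

  # conservation
  expect_identical(r$TP + r$FN, 10L)
  expect_identical(r$TN + r$FP, 10L)
})

test_that("undefined denominators give NA rates, not zero", {
  no_neg <- summarize_eval(c(2.0, NA), c(2, 2.5))
  expect_true(is.na(no_neg$specificity) && is.na(no_neg$fpr))
  no_pos <- summarize_eval(c(NA, 1), c(NA, NA))
  expect_true(is.na(no_pos$sensitivity) && is.na(no_pos$fnr))
  expect_true(is.na(no_pos$rmse_s))
})

test_that("advance is antisymmetric between two methods", {
  a <- c(1.0, 2.0, NA, 3.0)
  b <- c(1.5, 1.8, 2.0, NA)
  truth <- c(1, 2, 3, 3)
  ab <- summarize_eval(a, truth, t_ref = b)$advance_s
  ba <- summarize_eval(b, truth, t_ref = a)$advance_s
  expect_equal(ab, -ba)
})

test_that("benchmark reports are complete, bounded and order-invariant", {
  ds <- make_benchmark_set(6, seed0 = 400, duration = 4)
  methods <- c("mse", "threshold", "rms")
  rep1 <- run_benchmark(ds, methods = methods, reject_delta = 0.02)
  expect_identical(rep1$metrics$method, methods)
  rates <- unlist(rep1$metrics[, c("sensitivity", "specificity", "fnr", "fpr")])
  rates <- rates[!is.na(rates)]
  expect_true(all(rates >= 0 & rates <= 1))
  expect_identical(nrow(rep1$onsets), 6L)
  expect_equal(rep1$metrics$advance_s[rep1$metrics$method == "threshold"], 0)

  rep2 <- run_benchmark(ds, methods = methods, reject_delta = 0.02)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$onsets, rep2$onsets)

  shuffled <- ds[c(4, 1, 6, 2, 5, 3)]
  rep3 <- run_benchmark(shuffled, methods = methods, reject_delta = 0.02)
  expect_identical(rep3$metrics[, -1], rep1$metrics[, -1])
})

test_that("benchmark reports serialize to delimited text", {
  ds <- make_benchmark_set(2, seed0 = 500, duration = 4)
  rep <- run_benchmark(ds, methods = c("threshold", "rms"))
  stem <- tempfile()
  paths <- write_benchmark_report(rep, stem)
  m <- read.delim(paste0(stem, "_metrics.tsv"))
  expect_identical(nrow(m), 2L)
  o <- read.delim(paste0(stem, "_onsets.tsv"), check.names = FALSE)
  expect_identical(nrow(o), 2L)
  expect_true(all(c("threshold", "rms") %in% names(o)))
})

test_that("truth can be re-referenced to the ramp midpoint", {
  ds <- make_benchmark_set(2, seed0 = 600, duration = 4)
  r_start <- run_benchmark(ds, methods = "threshold", truth_ref = "start")
  r_mid <- run_benchmark(ds, methods = "threshold", truth_ref = "mid")
  pos <- !is.na(r_start$onsets$t_true)
  expect_true(all(r_mid$onsets$t_true[pos] > r_start$onsets$t_true[pos]))
})
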
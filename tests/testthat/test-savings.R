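mk_metric <- function(values, start = 2L, name = "delta") {
  fidnavQC:::MotionMetricSeries(values, start, name)
}

test_that("running score accumulates to the integrated score", {
  m <- mk_metric(runif(19, 0, 0.5))
  r <- runningScore(m, 20, 1.54)
  expect_equal(r[length(r)], scoreValue(integrateScore(m, 20, 1.54)))
  expect_true(all(diff(r) >= 0))
  # unit trace, n = 100, TR = 1: value at step i is (i - 1)/100
  m1 <- mk_metric(rep(1, 99))
  r1 <- runningScore(m1, 100, 1)
  expect_equal(r1, (2:100 - 1) / 100, ignore_attr = TRUE)
  expect_equal(attr(r1, "steps"), 2:100)
  expect_equal(runningScore(mk_metric(rep(0, 5)), 6, 1), rep(0, 5),
               ignore_attr = TRUE)
  expect_error(runningScore(mk_metric(numeric(0)), 5, 1), "empty")
})

test_that("abort decisions record FR and FA correctly", {
  # never crossed
  r <- structure(seq(0, 0.1, length.out = 10), steps = 2:11)
  d <- abortDecision(r, 5, 100)
  expect_false(d$detected)
  expect_true(is.na(d$fa) && is.na(d$fr))
  # crossing at step 20 of 100
  r2 <- structure(c(rep(0, 10), rep(1, 10)), steps = 11:30)
  d2 <- abortDecision(r2, 0.5, 100)
  expect_true(d2$detected)
  expect_equal(d2$crossing_step, 21L)
  expect_equal(d2$fa, 0.21)
  expect_equal(d2$fr, 0.79)
  expect_equal(d2$fa + d2$fr, 1)
  # near-zero threshold triggers at the first defined step
  r3 <- structure(rep(0.3, 5), steps = 2:6)
  d3 <- abortDecision(r3, 1e-9, 10)
  expect_equal(d3$crossing_step, 2L)
  expect_equal(d3$fa, 0.2)
  expect_error(abortDecision(r3, 0, 10), "positive")
})

test_that("time savings reproduce the hand-worked cohort cases", {
  # no detections -> 0%
  out <- data.frame(positive = c(TRUE, FALSE), detected = FALSE,
                    fa = NA_real_, fr = NA_real_)
  expect_equal(timeSavings(out)$t_savings_pct, 0)
  # 1 TP (FR = 0.8) + 1 TN: denominator 2*1 + 1 = 3 -> 26.67%
  out2 <- data.frame(positive = c(TRUE, FALSE),
                     detected = c(TRUE, FALSE),
                     fa = c(0.2, NA), fr = c(0.8, NA))
  ts2 <- timeSavings(out2)
  expect_equal(ts2$t_savings_pct, 100 * 0.8 / 3)
  expect_equal(ts2$t_savings_pct, 26.67, tolerance = 1e-3)
  # adding an FP with FA = 0.8 cancels the numerator; denominator 4
  out3 <- rbind(out2, data.frame(positive = FALSE, detected = TRUE,
                                 fa = 0.8, fr = 0.2))
  ts3 <- timeSavings(out3)
  expect_equal(ts3$t_savings_pct, 0)
  expect_equal(ts3$n_fp, 1)
  # the printed-grouping switch counts undetected positives once
  out4 <- data.frame(positive = c(TRUE, TRUE, FALSE),
                     detected = c(TRUE, FALSE, FALSE),
                     fa = c(0.2, NA, NA), fr = c(0.8, NA, NA))
  expect_equal(timeSavings(out4)$t_savings_pct, 100 * 0.8 / 5)
  expect_equal(timeSavings(out4, grouping = "printed")$t_savings_pct,
               100 * 0.8 / 4)
  expect_error(timeSavings(out4[0, ]), "empty")
})

test_that("cost report reproduces the repeat-scan arithmetic", {
  # 12 non-diagnostic scans at 4.2 min, $2828 per 45-min slot
  grades <- rep(c(1, 2, 3, 4, 5), c(3, 9, 12, 29, 49))
  rep0 <- costReport(grades, outcomes = NULL)
  expect_equal(rep0@repeatMinutes, 12 * 4.2)
  expect_equal(round(rep0@repeatMinutes), 50)
  expect_equal(round(rep0@repeatCost), 3167)
  expect_equal(rep0@costPerMinute, 2828 / 45)
  # no non-diagnostic scans -> no repeat cost
  expect_equal(costReport(c(3, 4, 5), NULL)@repeatCost, 0)
  # saved/wasted minutes at the per-minute rate
  out <- data.frame(positive = c(TRUE, FALSE, FALSE),
                    detected = c(TRUE, TRUE, FALSE),
                    fa = c(0.1, 0.5, NA), fr = c(0.9, 0.5, NA))
  rp <- costReport(c(1, 4, 5), out)
  expect_equal(rp@minutesSaved, 0.9 * 4.2)
  expect_equal(rp@minutesWasted, 0.5 * 4.2)
  expect_equal(rp@netCostSaving, (0.9 - 0.5) * 4.2 * 2828 / 45)
  # TA -> 0 drives every dollar and minute quantity to zero
  z <- costReport(c(1, 4, 5), out, costModel(ta_minutes = 0))
  expect_equal(z@minutesSaved + z@minutesWasted + z@repeatCost +
                 z@netCostSaving, 0)
})

test_that("savings-optimal threshold attains the exhaustive-grid maximum", {
  n <- 50; tr <- 1
  # one early-crossing TP, one late-crossing FP, one TN
  tp <- mk_metric(c(rep(2, 10), rep(0, 39)))
  fp <- mk_metric(c(rep(0, 39), rep(1, 10)))
  tn <- mk_metric(rep(0.001, 49))
  metrics <- list(tp, fp, tn)
  positive <- c(TRUE, FALSE, FALSE)
  opt <- optimizeThresholdForSavings(metrics, positive, n, tr)
  # oracle: exhaustive evaluation over the candidate grid (all final
  # integrated scores plus midpoints between consecutive candidates)
  finals <- sort(unique(vapply(metrics, function(m)
    sum(metricValues(m)) / n, numeric(1))))
  grid <- sort(unique(c(finals, (head(finals, -1) + tail(finals, -1)) / 2)))
  grid_best <- max(vapply(grid, function(th) {
    outc <- cohortAbortOutcomes(metrics, positive, th, n, tr)
    timeSavings(outc)$t_savings_pct
  }, numeric(1)))
  expect_equal(opt$t_savings_pct, grid_best)
  # the chosen threshold aborts the TP but not the FP
  outc <- cohortAbortOutcomes(metrics, positive, opt$threshold, n, tr)
  expect_true(outc$detected[1])
  expect_false(outc$detected[2])
  # threshold above all scores yields zero savings
  outc0 <- cohortAbortOutcomes(metrics, positive, 10 * max(finals), n, tr)
  expect_equal(timeSavings(outc0)$t_savings_pct, 0)
})

test_that("tie-breaking picks the largest of equally good thresholds", {
  # the positive subject's running score jumps to its final value in one
  # step, so every candidate it crosses yields identical savings; the
  # negative subject's score is far below all of them
  a <- mk_metric(c(9, rep(0, 8)))   # running score 0.9 from step 2 on
  b <- mk_metric(rep(0.01, 9))      # final score 0.009
  opt <- optimizeThresholdForSavings(list(a, b), c(TRUE, FALSE), 10, 1)
  expect_equal(opt$threshold, 0.9)
})

test_that("detected outcomes always satisfy FR + FA = 1", {
  set.seed(17)
  metrics <- lapply(1:8, function(i) mk_metric(runif(19, 0, 0.3)))
  positive <- rep(c(TRUE, FALSE), 4)
  outc <- cohortAbortOutcomes(metrics, positive, 0.05, 20, 1.54)
  det <- outc[outc$detected, ]
  expect_true(nrow(det) > 0)
  expect_equal(det$fr + det$fa, rep(1, nrow(det)))
})
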
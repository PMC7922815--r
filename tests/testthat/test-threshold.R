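# Geometric series, PAVA smoothing, threshold interpolation and the
# psychometric fit.

test_that("geometric series reproduce the published dose ladder", {
  expect_equal(makeGeometricSeries(0.614, 2, 5),
               c(0.614, 1.228, 2.456, 4.912, 9.824))
  expect_equal(makeGeometricSeries(1, 2, 3), c(1, 2, 4))
  # the printed ladder doubles per step (upper run exactly; the printed
  # low-end values carry inconsistent rounding, so they are data)
  printed <- interactionDoses()
  expect_equal(makeGeometricSeries(0.614, 2, 5), printed[5:9])
  expect_true(all(abs(diff(log2(printed)) - 1) < 0.05))
  expect_error(makeGeometricSeries(1, 1, 5),
               class = "pyrasense_design_error")
  expect_error(makeGeometricSeries(-1, 2, 5),
               class = "pyrasense_design_error")
})

test_that("internal PAVA agrees with the recursive oracle and isoreg", {
  y <- c(0.2, 0.6, 0.5, 0.9)
  expect_equal(pyrasense:::.pava(y), c(0.2, 0.55, 0.55, 0.9))
  set.seed(7)
  for (i in 1:20) {
    y <- runif(8)
    expect_equal(pyrasense:::.pava(y), isoreg(y)$yf, tolerance = 1e-12)
  }
  # weighted pooling: heavier point dominates the pooled value
  expect_equal(pyrasense:::.pava(c(0.8, 0.2), w = c(3, 1)),
               rep(0.65, 2))
})

test_that("threshold interpolation is log-linear between bracketing doses", {
  cur <- DetectionCurve(c(0.1, 0.2), n = 10, k = c(4, 6))
  est <- estimateThreshold(cur)
  expect_equal(thresholdValue(est), 10^(-1 + 0.5 * log10(2)),
               tolerance = 1e-12)
  expect_equal(est@bracket, c(0.1, 0.2))
  # an exact hit returns the dose itself
  hit <- estimateThreshold(DetectionCurve(c(1, 2, 4), 10, c(2, 5, 9)))
  expect_equal(thresholdValue(hit), 2)
  # monotone violations are PAVA-smoothed before interpolation
  smoothed <- estimateThreshold(
    DetectionCurve(c(1, 2, 4, 8), 10, c(2, 6, 5, 9)))
  expect_equal(smoothed@bracket, c(1, 2))
  expect_equal(thresholdValue(smoothed),
               10^(0 + (0.5 - 0.2) / (0.55 - 0.2) * log10(2)))
})

test_that("threshold estimation handles censoring and no-crossing", {
  high <- DetectionCurve(c(1, 2, 4), 20, c(15, 18, 20))
  est <- estimateThreshold(high)
  expect_equal(est@censored, "left")
  expect_equal(thresholdValue(est), 1)
  low <- DetectionCurve(c(1, 2, 4), 20, c(5, 6, 7))
  err <- tryCatch(estimateThreshold(low), condition = identity)
  expect_s3_class(err, "pyrasense_no_crossing")
  expect_equal(err$maxProportion, 0.35)
})

test_that("threshold is dose-equivariant and monotone in the criterion", {
  cur <- DetectionCurve(c(0.5, 1, 2, 4, 8), 20,
                        k = c(6, 8, 11, 16, 19))
  t1 <- thresholdValue(estimateThreshold(cur))
  for (f in c(0.1, 3)) {
    scaled <- DetectionCurve(f * doses(cur), 20, nCorrect(cur))
    expect_equal(thresholdValue(estimateThreshold(scaled)), f * t1,
                 tolerance = 1e-10)
  }
  crits <- c(0.4, 0.5, 0.6, 0.7)
  vals <- vapply(crits, function(cr)
    thresholdValue(estimateThreshold(cur, criterion = cr)), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("simulated curves recover the generating threshold", {
  series <- interactionDoses()
  cfg <- studyConfig()
  est <- vapply(1:60, function(i) {
    cur <- simulateAfcResponses(series, 0.456, cfg, seed = i)
    thresholdValue(estimateThreshold(cur, scale = "chance_corrected"))
  }, numeric(1))
  # median within one dilution step (factor 2) of the generating value
  expect_lt(abs(log2(median(est) / 0.456)), 1)
})

test_that("the psychometric MLE recovers a known midpoint", {
  series <- makeGeometricSeries(0.0384, 2, 9)
  cfg <- studyConfig(nPanelists = 60, panelistGsd = 0)
  cur <- simulateAfcResponses(series, 0.456, cfg, seed = 5)
  fit <- fitPsychometric(cur)
  expect_lt(abs(fit$midpoint - log10(0.456)), 0.1)
  expect_false(fit$boundary)
  # fitted threshold sits at the (1 + chance)/2 correct level
  pAt <- 1 / 3 + 2 / 3 * plogis(fit$slope * (log10(fit$threshold) -
                                               fit$midpoint))
  expect_equal(pAt, (1 + 1 / 3) / 2)
})

test_that("degenerate psychometric data raise fit errors or flags", {
  flat <- DetectionCurve(c(1, 2, 4), 30, k = c(10, 10, 10))
  expect_error(fitPsychometric(flat), class = "pyrasense_fit_error")
  sat <- DetectionCurve(c(1, 2, 4), 30, k = c(30, 30, 30))
  expect_error(fitPsychometric(sat), class = "pyrasense_fit_error")
  step <- DetectionCurve(c(1, 2, 4, 8), 40, k = c(13, 14, 40, 40))
  expect_warning(fit <- fitPsychometric(step), "boundary")
  expect_true(fit$boundary)
})
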
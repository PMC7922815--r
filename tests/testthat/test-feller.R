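# Feller additive model and the interaction verdict.

test_that("fellerPredict follows the additive-independence formula", {
  expect_equal(fellerPredict(0.5, 0.5), 0.75)
  expect_equal(fellerPredict(0, 0.37), 0.37)
  expect_equal(fellerPredict(0.3, 0.4), 0.58)
  expect_error(fellerPredict(-0.1, 0.5), class = "pyrasense_domain_error")
  expect_error(fellerPredict(0.5, 1.2), class = "pyrasense_domain_error")
})

test_that("Feller invariants hold over a randomized probability grid", {
  set.seed(99)
  p <- runif(200); q <- runif(200)
  pab <- fellerPredict(p, q)
  # commutative
  expect_equal(pab, fellerPredict(q, p), tolerance = 1e-15)
  # complement-product identity
  expect_equal(1 - pab, (1 - p) * (1 - q), tolerance = 1e-12)
  # never below either component; equality iff the other is 0
  expect_true(all(pab >= pmax(p, q) - 1e-15))
  expect_equal(fellerPredict(0, q), q)
  strict <- p > 0 & q > 0
  expect_true(all(pab[strict] > pmax(p, q)[strict]))
})

test_that("threshold ratios reproduce the published factors", {
  expect_equal(roundHalfUp(thresholdRatio(0.456, 0.143), 1), 3.2)
  expect_equal(roundHalfUp(thresholdRatio(0.292, 0.143), 1), 2.0)
  expect_equal(thresholdRatio(0.7, 0.7), 1)
  expect_error(thresholdRatio(0, 1), class = "pyrasense_domain_error")
})

test_that("an exactly additive curve is called additive with ratio near 1", {
  dose <- makeGeometricSeries(0.05, 2, 9)
  pB <- plogis(4.9 * (log10(dose) - log10(0.456)))
  pc <- function(pd) round(20 * (1 / 3 + 2 / 3 * pd))
  kB <- pc(pB)
  # mixture exactly at the Feller prediction with pA = 0
  pair <- makePair(dose, kB = kB, kAB = kB)
  v <- classifyInteraction(pair, pAMode = "zero", seed = 1)
  expect_equal(interactionCall(v), "additive")
  expect_equal(v@ratio, 1, tolerance = 0.15)
  expect_equal(v@predicted$predicted_correct,
               v@predicted$observed_correct, tolerance = 0.05)
})

test_that("verdict inputs are validated", {
  dose <- c(1, 2, 4)
  pair <- makePair(dose, kB = c(8, 12, 16), kAB = c(9, 13, 17))
  expect_error(classifyInteraction(pair, pAMode = "measured"),
               class = "pyrasense_design_error")
  short <- makePair(c(1, 2), kB = c(8, 12), kAB = c(9, 13))
  expect_error(classifyInteraction(short, pAMode = "zero"),
               class = "pyrasense_design_error")
  expect_error(MixturePair(DetectionCurve(c(1, 2), 10, c(3, 4)),
                           DetectionCurve(c(1, 3), 10, c(3, 4))))
})

test_that("censored curves yield a flagged verdict, not an error", {
  dose <- c(1, 2, 4)
  pair <- makePair(dose, kB = c(7, 8, 9), kAB = c(7, 8, 8), n = 20)
  v <- classifyInteraction(pair, pAMode = "zero", seed = 2)
  expect_true(v@thresholdObserved@censored == "right")
  expect_true(is.na(v@ratio))
  expect_s4_class(v, "InteractionVerdict")
})

test_that("per-dose detail reports exact binomial comparisons", {
  dose <- c(1, 2, 4, 8)
  pair <- makePair(dose, kB = c(7, 10, 14, 18), kAB = c(8, 11, 15, 19))
  v <- classifyInteraction(pair, pAMode = "zero", nBoot = 200, seed = 3)
  dt <- v@doseTests
  expect_equal(nrow(dt), 4L)
  expect_equal(dt$p_upper,
               pbinom(dt$k - 1, dt$n, dt$predicted_correct,
                      lower.tail = FALSE))
  expect_true(all(dt$p_two_sided >= pmin(dt$p_upper, dt$p_lower)))
})

test_that("the verdict is reproducible under a fixed seed", {
  cfg <- studyConfig(panelistGsd = 0, theta = 2)
  mp <- simulateMixtureExperiment(interactionDoses(), 0.456, cfg,
                                  seed = 77)
  v1 <- classifyInteraction(mp, pAMode = "measured", nBoot = 500,
                            seed = 9)
  v2 <- classifyInteraction(mp, pAMode = "measured", nBoot = 500,
                            seed = 9)
  expect_equal(v1@pValue, v2@pValue)
  expect_equal(interactionCall(v1), interactionCall(v2))
})
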
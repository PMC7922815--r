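# Calibration fitting, inverse prediction, recovery, RSD and LOD/LOQ.

test_that("noiseless calibration lines are recovered exactly", {
  conc <- c(5, 10, 50, 100, 500)
  fit <- fitCalibration(data.frame(concentration = conc,
                                   ratio = 0.01 * conc))
  expect_equal(fit@slope, 0.01, tolerance = 1e-12)
  expect_equal(fit@intercept, 0, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_true(fit@linear)

  # two points define the line whatever the noise
  fit2 <- fitCalibration(data.frame(concentration = c(0, 80),
                                    ratio = c(0, 1.36)))
  expect_equal(fit2@slope, 1.36 / 80)
  expect_equal(fit2@rSquared, 1)
})

test_that("noisy calibration agrees with the closed-form OLS oracle", {
  series <- simulateCalibration(slope = 0.02, noiseSd = 0.001,
                                concentrations = c(1, 5, 10, 50, 100, 500,
                                                   1000), seed = 11)
  fit <- fitCalibration(series)
  oracle <- olsClosed(series$concentration, series$ratio)
  expect_equal(fit@slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit@intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  # fitted slope within 3 standard errors of truth
  se <- sqrt(sum((series$ratio - fit@intercept -
                    fit@slope * series$concentration)^2) / 5 /
               sum((series$concentration - mean(series$concentration))^2))
  expect_lt(abs(fit@slope - 0.02), 3 * se)
  # analyte/IS input form gives the same fit
  fit3 <- fitCalibration(series[c("concentration", "analyte",
                                  "internalStandard")])
  expect_equal(fit3@slope, fit@slope)
})

test_that("degenerate calibration designs are rejected", {
  expect_error(fitCalibration(data.frame(concentration = c(10, 10),
                                         ratio = c(0.1, 0.11))),
               class = "pyrasense_design_error")
  expect_error(
    fitCalibration(data.frame(concentration = c(1, 10),
                              analyte = c(1, 2),
                              internalStandard = c(0, 1))),
    class = "pyrasense_data_error")
})

test_that("inverse prediction inverts the forward map and flags negatives", {
  fit <- fitCalibration(data.frame(concentration = c(0, 1000),
                                   ratio = c(0, 10)))  # slope 0.01
  expect_equal(as.numeric(quantifyConcentration(fit, 5.2157)), 521.57)
  expect_equal(as.numeric(quantifyConcentration(fit, fit@intercept)), 0)
  expect_warning(out <- quantifyConcentration(fit, -0.5))
  expect_true(attr(out, "belowZero"))
  expect_lt(as.numeric(out), 0)  # preserved, not clamped
  degenerate <- new("CalibrationFit", slope = 0, intercept = 0,
                    rSquared = 1, linear = TRUE, lod = NA_real_,
                    loq = NA_real_, n = 2L, weighting = "none")
  expect_error(quantifyConcentration(degenerate, 1),
               class = "pyrasense_degenerate_model")
})

test_that("recovery follows the spiked-minus-unspiked formula", {
  expect_equal(computeRecovery(150, 50, 100), 100)
  expect_equal(computeRecovery(134.36, 50, 100), 84.36)
  expect_equal(computeRecovery(50, 50, 100), 0)
  # invariant under common rescaling
  expect_equal(computeRecovery(134.36, 50, 100),
               computeRecovery(1343.6, 500, 1000))
  expect_error(computeRecovery(1, 1, 0), class = "pyrasense_design_error")
})

test_that("RSD is sd/mean in percent and scale-invariant", {
  expect_equal(computeRSD(c(100, 100, 100)), 0)
  expect_equal(computeRSD(c(98, 100, 102)), 2)
  expect_equal(computeRSD(c(98, 100, 102)), computeRSD(7 * c(98, 100, 102)))
  expect_error(computeRSD(100), class = "pyrasense_design_error")
  expect_error(computeRSD(c(0, 0)), class = "pyrasense_undefined_rsd")
})

test_that("LOD/LOQ follow the S/N 3 and 10 definition", {
  expect_equal(estimateLodLoq(1, 1), c(lod = 3, loq = 10))
  expect_equal(estimateLodLoq(0, 0.5), c(lod = 0, loq = 0))
  expect_equal(estimateLodLoq(0.5, 0.01), c(lod = 150, loq = 500))
  # loq/lod is exactly 10/3 whenever defined
  for (ns in c(0.01, 0.3, 2)) {
    ll <- estimateLodLoq(ns, 0.037)
    expect_equal(unname(ll["loq"] / ll["lod"]), 10 / 3)
  }
  expect_error(estimateLodLoq(1, 0), class = "pyrasense_design_error")
})

test_that("simulated calibration series pass the linearity gate at low noise", {
  # sigma chosen small relative to the span so expected R^2 clears 0.99
  fit <- fitCalibration(simulateCalibration(slope = 0.01, noiseSd = 0.02,
                                            seed = 3))
  expect_true(fit@linear)
  noisy <- fitCalibration(simulateCalibration(slope = 0.01, noiseSd = 5,
                                              seed = 3))
  expect_false(noisy@linear)
})
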
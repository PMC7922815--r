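# Targeted-quantitation QC: calibration, inverse prediction, recovery,
# replicate RSD and signal-to-noise based LOD/LOQ.

#' Fit a calibration curve on the internal-standard response ratio
#'
#' Least squares of the analyte / internal-standard response ratio on the
#' known concentration. Unweighted by default; `weighting = "one_over_x"`
#' applies 1/concentration weights (zero-concentration levels get the
#' smallest positive level's weight). A linearity flag marks fits whose
#' coefficient of determination falls below the 0.99 acceptance gate.
#'
#' @param series data.frame with columns `concentration` (ug/L),
#'   `analyte` and `internalStandard` (arbitrary area units), or
#'   `concentration` and `ratio` directly.
#' @param weighting `"none"` (default) or `"one_over_x"`.
#' @param noiseSd optional baseline noise standard deviation on the
#'   response-ratio scale; when given, LOD/LOQ are derived via
#'   [estimateLodLoq()].
#' @return a [CalibrationFit-class].
#' @export
#' @examples
#' s <- data.frame(concentration = c(10, 50, 100, 500),
#'                 ratio = 0.01 * c(10, 50, 100, 500))
#' fitCalibration(s)
fitCalibration <- function(series, weighting = c("none", "one_over_x"),
                           noiseSd = NULL) {
  weighting <- match.arg(weighting)
  if (!"concentration" %in% names(series))
    .err("calibration series needs a 'concentration' column",
         "pyrasense_data_error")
  conc <- series$concentration
  if ("ratio" %in% names(series)) {
    ratio <- series$ratio
  } else {
    if (!all(c("analyte", "internalStandard") %in% names(series)))
      .err("need 'ratio' or both 'analyte' and 'internalStandard' columns",
           "pyrasense_data_error")
    if (any(series$internalStandard <= 0))
      .err("internal standard response must be > 0 at every level",
           "pyrasense_data_error")
    if (any(series$analyte < 0))
      .err("analyte responses must be >= 0", "pyrasense_data_error")
    ratio <- series$analyte / series$internalStandard
  }
  if (length(unique(conc)) < 2L)
    .err("at least 2 distinct concentration levels are required",
         "pyrasense_design_error")
  w <- NULL
  if (weighting == "one_over_x") {
    wConc <- conc
    wConc[wConc <= 0] <- min(conc[conc > 0])
    w <- 1 / wConc
  }
  fit <- lm(ratio ~ conc, weights = w)
  co <- unname(coef(fit))
  # R^2 on the (weighted) fit; exact-fit designs give 1 by construction
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 1
  r2 <- min(max(r2, 0), 1)
  lodloq <- c(NA_real_, NA_real_)
  if (!is.null(noiseSd)) lodloq <- estimateLodLoq(noiseSd, co[2])
  new("CalibrationFit", slope = co[2], intercept = co[1], rSquared = r2,
      linear = r2 >= 0.99, lod = lodloq[[1]], loq = lodloq[[2]],
      n = length(conc), weighting = weighting)
}

#' Inverse-predict a concentration from a response ratio
#'
#' Returns `(ratio - intercept) / slope`. Negative predictions are
#' returned as-is with a `belowZero` attribute (and a warning) rather than
#' silently clamped; reporting layers may display them as 0.
#'
#' @param fit a [CalibrationFit-class] (or anything with `slope` /
#'   `intercept` slots).
#' @param ratio numeric response ratio(s).
#' @return numeric concentration(s), with logical attribute `belowZero`.
#' @export
quantifyConcentration <- function(fit, ratio) {
  if (!is.finite(fit@slope) || fit@slope == 0)
    .err("degenerate calibration model: slope is zero",
         "pyrasense_degenerate_model")
  conc <- (ratio - fit@intercept) / fit@slope
  below <- conc < 0
  if (any(below)) {
    warning(sprintf("%d prediction(s) below zero; flagged, not clamped",
                    sum(below)))
  }
  structure(conc, belowZero = below)
}

#' Spike recovery
#'
#' `(measured spiked - measured unspiked) / added * 100` (%). May exceed
#' 100; invariant under common rescaling of all three arguments.
#'
#' @param measuredSpiked,measuredUnspiked measured concentrations (ug/L).
#' @param added spiked amount (ug/L), must be > 0.
#' @return recovery percentage.
#' @export
#' @examples
#' computeRecovery(134.36, 50, 100)  # 84.36
computeRecovery <- function(measuredSpiked, measuredUnspiked, added) {
  if (any(added <= 0))
    .err("added concentration must be > 0", "pyrasense_design_error")
  (measuredSpiked - measuredUnspiked) / added * 100
}

#' Relative standard deviation of replicates
#'
#' `100 * sd / mean` over replicate concentrations (sample sd, n - 1
#' denominator). Triplicates are the usual design but any n >= 2 is
#' accepted.
#'
#' @param replicates numeric vector of replicate concentrations.
#' @return RSD in percent.
#' @export
computeRSD <- function(replicates) {
  if (length(replicates) < 2L)
    .err("at least 2 replicates are required", "pyrasense_design_error")
  m <- mean(replicates)
  if (!is.finite(m) || m <= 0)
    .err("RSD is undefined for non-positive mean", "pyrasense_undefined_rsd")
  100 * sd(replicates) / m
}

#' LOD and LOQ from baseline noise and calibration slope
#'
#' Concentrations at which the expected signal reaches 3 and 10 times the
#' baseline noise: `lod = 3 * noiseSd / slope`, `loq = 10 * noiseSd /
#' slope`, so `loq / lod = 10 / 3` exactly.
#'
#' @param noiseSd baseline noise sd in response(-ratio) units, >= 0.
#' @param slope calibration slope (response per ug/L), > 0.
#' @return named numeric `c(lod =, loq =)` in ug/L.
#' @export
estimateLodLoq <- function(noiseSd, slope) {
  if (any(slope <= 0))
    .err("slope must be > 0", "pyrasense_design_error")
  if (any(noiseSd < 0))
    .err("noise sd must be >= 0", "pyrasense_design_error")
  c(lod = 3 * noiseSd / slope, loq = 10 * noiseSd / slope)
}
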
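# Core S4 classes. The concentration/threshold container extends
# SummarizedExperiment (compounds in rows, Baijiu samples in columns);
# psychophysical results get small dedicated classes.

#' AromaExperiment: concentrations plus odor thresholds
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a
#' compounds-by-samples concentration matrix (assay `"concentration"`,
#' ug/L; missing values allowed) with per-compound odor thresholds in
#' `rowData` (`threshold` in ug/L, plus the `matrix` the threshold was
#' measured in and its `source`). An optional `"rsd"` assay carries the
#' replicate relative standard deviations (%).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [AromaExperiment()] (constructor), [oav()], [oavProfile()],
#'   [ssabExperiment()]
#' @export
setClass("AromaExperiment", contains = "SummarizedExperiment")

setValidity("AromaExperiment", function(object) {
  msgs <- character(0)
  if (!"concentration" %in% assayNames(object))
    msgs <- c(msgs, "assay 'concentration' is required")
  else {
    conc <- assay(object, "concentration")
    if (any(conc < 0, na.rm = TRUE))
      msgs <- c(msgs, "concentrations must be >= 0")
  }
  rd <- rowData(object)
  if (!"threshold" %in% colnames(rd))
    msgs <- c(msgs, "rowData column 'threshold' is required")
  else if (any(!is.finite(rd$threshold) | rd$threshold <= 0))
    msgs <- c(msgs, "odor thresholds must be finite and > 0")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "compound identifiers must be unique")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample identifiers must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Detection curve from an ascending 3-AFC series
#'
#' Per-dose panel counts for a forced-choice detection experiment: at each
#' dose, `n` panelists made a 3-AFC judgement and `k` chose the spiked
#' sample. Proportion-correct and the Abbott chance-corrected detection
#' probability are derived, not stored.
#'
#' @slot dose numeric, strictly increasing, positive dose magnitudes
#'   (mL of stock into 15 mL matrix, or ug/L).
#' @slot n integer, panelists per dose.
#' @slot k integer, correct choices per dose.
#' @slot chance numeric guessing probability (1/3 for 3-AFC).
#' @seealso [DetectionCurve()], [estimateThreshold()], [fitPsychometric()]
#' @export
setClass("DetectionCurve",
         representation(dose = "numeric", n = "integer", k = "integer",
                        chance = "numeric"))

setValidity("DetectionCurve", function(object) {
  msgs <- character(0)
  d <- object@dose
  if (length(d) == 0) msgs <- c(msgs, "at least one dose is required")
  if (any(!is.finite(d) | d <= 0)) msgs <- c(msgs, "doses must be > 0")
  if (is.unsorted(d, strictly = TRUE)) msgs <- c(msgs, "doses must be strictly increasing")
  if (length(object@n) != length(d) || length(object@k) != length(d))
    msgs <- c(msgs, "dose, n and k must have equal length")
  else if (any(object@k < 0L | object@k > object@n))
    msgs <- c(msgs, "counts must satisfy 0 <= k <= n")
  if (length(object@chance) != 1 || object@chance <= 0 || object@chance >= 1)
    msgs <- c(msgs, "chance must be a single probability in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Group odor-threshold estimate
#'
#' Result of [estimateThreshold()]: the dose at which the detection curve
#' crosses the criterion, with the bracketing doses, the scale the
#' criterion was applied on, and censoring flags.
#'
#' @slot value numeric threshold in dose units (NA when no crossing).
#' @slot criterion numeric criterion probability in (0, 1).
#' @slot scale `"raw_correct"` or `"chance_corrected"`.
#' @slot method estimation method label.
#' @slot bracket numeric length-2 doses bracketing the crossing.
#' @slot censored `"none"`, `"left"` (curve already above criterion at
#'   the lowest dose, so the threshold is at most `value`) or `"right"`
#'   (criterion never reached; `value` is NA).
#' @export
setClass("ThresholdEstimate",
         representation(value = "numeric", criterion = "numeric",
                        scale = "character", method = "character",
                        bracket = "numeric", censored = "character"))

#' Component and mixture detection curves for an interaction analysis
#'
#' Bundles the dose-varying component B curve, the observed mixture (AB)
#' curve on the same dose axis, and optionally the fixed-composition
#' component A counts (a single 3-AFC test of the sub-threshold bundle).
#'
#' @slot componentA list: either empty or `list(n =, k =)` pooled counts
#'   for the fixed bundle.
#' @slot componentB a [DetectionCurve].
#' @slot mixture a [DetectionCurve] on the identical dose axis.
#' @seealso [MixturePair()], [classifyInteraction()]
#' @export
setClass("MixturePair",
         representation(componentA = "list", componentB = "DetectionCurve",
                        mixture = "DetectionCurve"))

setValidity("MixturePair", function(object) {
  msgs <- character(0)
  if (!isTRUE(all.equal(object@componentB@dose, object@mixture@dose)))
    msgs <- c(msgs, "component B and mixture must share an identical dose axis")
  a <- object@componentA
  if (length(a) && (!all(c("n", "k") %in% names(a)) ||
                    a$k < 0 || a$k > a$n))
    msgs <- c(msgs, "componentA must be empty or list(n =, k =) with 0 <= k <= n")
  if (length(msgs)) msgs else TRUE
})

#' Verdict of a Feller additive-model comparison
#'
#' Output of [classifyInteraction()]: the dose-wise Feller-predicted
#' mixture curve, observed and predicted thresholds, their ratio, the
#' synergy/additive/suppression call with its calibrated p-value, and the
#' per-dose exact-binomial detail table.
#'
#' @slot call one of `"synergy"`, `"additive"`, `"suppression"`.
#' @slot ratio predicted/observed threshold ratio (> 1 means the mixture
#'   is detected at lower doses than independence predicts).
#' @slot thresholdObserved,thresholdPredicted [ThresholdEstimate]s.
#' @slot predicted data.frame of per-dose observed/predicted curves.
#' @slot doseTests data.frame of per-dose exact binomial comparisons.
#' @slot pValue bootstrap-calibrated two-sided p-value of the pooled
#'   deviation statistic.
#' @slot statistic the pooled deviation statistic (positive = observed
#'   detection above prediction).
#' @slot alpha decision level.
#' @slot pA detection probability used for the fixed component A.
#' @slot settings list echoing scale, criterion, pA mode, bootstrap size,
#'   seed.
#' @export
setClass("InteractionVerdict",
         representation(call = "character", ratio = "numeric",
                        thresholdObserved = "ThresholdEstimate",
                        thresholdPredicted = "ThresholdEstimate",
                        predicted = "data.frame", doseTests = "data.frame",
                        pValue = "numeric", statistic = "numeric",
                        alpha = "numeric", pA = "numeric",
                        settings = "list"))

#' Calibration fit for targeted quantitation
#'
#' Ordinary (optionally 1/x-weighted) least squares of the analyte /
#' internal-standard response ratio on known concentration, with the
#' linearity gate and signal-to-noise based LOD/LOQ.
#'
#' @slot slope,intercept regression coefficients (response ratio per ug/L,
#'   response ratio).
#' @slot rSquared coefficient of determination.
#' @slot linear TRUE when rSquared >= 0.99 (the acceptance gate used for
#'   the published curves).
#' @slot lod,loq ug/L at signal-to-noise 3 and 10 (NA when no noise sd was
#'   supplied).
#' @slot n number of calibration levels.
#' @slot weighting `"none"` or `"one_over_x"`.
#' @export
setClass("CalibrationFit",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", linear = "logical",
                        lod = "numeric", loq = "numeric", n = "integer",
                        weighting = "character"))
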
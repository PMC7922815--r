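# Constructors, accessors and show methods for the psychophysics classes.

#' Construct a detection curve
#'
#' @param dose strictly increasing positive dose magnitudes.
#' @param n panelists per dose (recycled if scalar).
#' @param k correct 3-AFC choices per dose.
#' @param chance guessing probability; 1/3 for a 3-AFC task.
#' @return a [DetectionCurve-class] object.
#' @export
#' @examples
#' DetectionCurve(dose = c(0.1, 0.2, 0.4), n = 20, k = c(7, 12, 18))
DetectionCurve <- function(dose, n, k, chance = 1/3) {
  n <- as.integer(rep_len(n, length(dose)))
  new("DetectionCurve", dose = as.numeric(dose), n = n,
      k = as.integer(k), chance = as.numeric(chance))
}

#' @describeIn DetectionCurve dose axis.
#' @param x,object a `DetectionCurve`.
#' @param ... unused.
#' @export
setMethod("doses", "DetectionCurve", function(x, ...) x@dose)

#' @describeIn DetectionCurve panelists per dose.
#' @export
setMethod("nPanelists", "DetectionCurve", function(x, ...) x@n)

#' @describeIn DetectionCurve correct choices per dose.
#' @export
setMethod("nCorrect", "DetectionCurve", function(x, ...) x@k)

#' @describeIn DetectionCurve observed proportion correct per dose.
#' @export
setMethod("pCorrect", "DetectionCurve", function(x, ...) x@k / x@n)

#' @describeIn DetectionCurve Abbott chance-corrected detection
#'   probability per dose (clipped below at 0).
#' @export
setMethod("pDetect", "DetectionCurve", function(x, ...)
  abbottCorrect(x@k / x@n, chance = x@chance))

#' @export
setMethod("length", "DetectionCurve", function(x) length(x@dose))

#' Coerce a detection curve to a per-dose data.frame
#'
#' @param x a [DetectionCurve-class].
#' @param ... unused.
#' @return data.frame with dose, n, k, p_correct, p_detect.
#' @export
setMethod("as.data.frame", "DetectionCurve", function(x, ...) {
  data.frame(dose = x@dose, n = x@n, k = x@k,
             p_correct = pCorrect(x), p_detect = pDetect(x))
})

setMethod("show", "DetectionCurve", function(object) {
  cat(sprintf("DetectionCurve: %d doses [%g .. %g], chance = %.3f\n",
              length(object@dose), min(object@dose), max(object@dose),
              object@chance))
  print(as.data.frame(object), row.names = FALSE, digits = 4)
})

#' @describeIn ThresholdEstimate the estimated threshold (dose units).
#' @param x,object a `ThresholdEstimate`.
#' @param ... unused.
#' @export
setMethod("thresholdValue", "ThresholdEstimate", function(x, ...) x@value)

setMethod("show", "ThresholdEstimate", function(object) {
  cens <- switch(object@censored, none = "", left = " (left-censored)")
  cat(sprintf(
    "ThresholdEstimate: %.4g%s\n  criterion %.2f on %s scale, %s\n  bracket [%.4g, %.4g]\n",
    object@value, cens, object@criterion, object@scale, object@method,
    object@bracket[1], object@bracket[2]))
})

#' Construct a mixture-experiment bundle
#'
#' @param componentB [DetectionCurve-class] of the dose-varying bundle
#'   alone.
#' @param mixture [DetectionCurve-class] of the mixture on the same dose
#'   axis.
#' @param componentA optional pooled counts for the fixed-composition
#'   bundle: `list(n =, k =)` or a `DetectionCurve` whose counts are
#'   pooled.
#' @return a [MixturePair-class].
#' @export
MixturePair <- function(componentB, mixture, componentA = NULL) {
  if (is(componentA, "DetectionCurve")) {
    componentA <- list(n = sum(componentA@n), k = sum(componentA@k))
  }
  if (is.null(componentA)) componentA <- list()
  new("MixturePair", componentA = componentA, componentB = componentB,
      mixture = mixture)
}

setMethod("show", "MixturePair", function(object) {
  cat(sprintf("MixturePair: %d doses", length(object@componentB@dose)))
  if (length(object@componentA)) {
    cat(sprintf("; component A counts %d/%d\n",
                object@componentA$k, object@componentA$n))
  } else cat("; component A not measured\n")
})

#' @describeIn InteractionVerdict the synergy/additive/suppression call.
#' @param x,object an `InteractionVerdict`.
#' @param ... unused.
#' @export
setMethod("interactionCall", "InteractionVerdict", function(x, ...) x@call)

setMethod("show", "InteractionVerdict", function(object) {
  cat("Feller additive-model comparison\n")
  cat(sprintf("  observed threshold : %.4g\n", object@thresholdObserved@value))
  cat(sprintf("  predicted threshold: %.4g\n", object@thresholdPredicted@value))
  if (is.finite(object@ratio)) {
    cat(sprintf("  threshold decreased by a factor of %.1f relative to the additive prediction\n",
                roundHalfUp(object@ratio, 1)))
  }
  cat(sprintf("  call: %s (pooled p = %.4g, alpha = %g)\n",
              object@call, object@pValue, object@alpha))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit (%d levels, %s weighting)\n  ratio = %.5g + %.5g * conc,  R^2 = %.5f%s\n",
    object@n, object@weighting, object@intercept, object@slope,
    object@rSquared,
    if (object@linear) "" else "  [below 0.99 linearity gate]"))
  if (is.finite(object@lod)) {
    cat(sprintf("  LOD = %.4g, LOQ = %.4g ug/L (S/N 3 and 10)\n",
                object@lod, object@loq))
  }
})
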
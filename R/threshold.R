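# Geometric dilution series and group odor-threshold estimation.

#' Build a geometric dose series
#'
#' `doses[i] = base * factor^(i-1)`, the uniform-on-log ladder used by
#' ascending forced-choice threshold work (factor 2 per step here). Full
#' precision is kept internally; reports round to 3 decimals. A published
#' printed ladder should be supplied verbatim as data rather than
#' regenerated, since printed low-end steps are often rounded
#' inconsistently.
#'
#' @param base first (lowest) dose, > 0.
#' @param factor step ratio, > 1.
#' @param nSteps number of doses, >= 2.
#' @return numeric dose vector.
#' @export
#' @examples
#' makeGeometricSeries(0.614, 2, 5)
makeGeometricSeries <- function(base, factor = 2, nSteps = 9) {
  if (base <= 0) .err("base dose must be > 0", "pyrasense_design_error")
  if (factor <= 1) .err("step factor must be > 1", "pyrasense_design_error")
  if (nSteps < 2) .err("need at least 2 steps", "pyrasense_design_error")
  base * factor^(seq_len(nSteps) - 1)
}

# internal: threshold by PAVA smoothing + linear interpolation on log-dose,
# operating on plain proportions (shared by observed and model-predicted
# curves).
.thresholdFromProportions <- function(dose, prop, weights, criterion,
                                      scale, method) {
  sm <- .pava(prop, weights)
  hit <- which(abs(sm - criterion) < 1e-9)
  if (length(hit)) {
    d <- dose[hit[1]]
    return(new("ThresholdEstimate", value = d, criterion = criterion,
               scale = scale, method = method, bracket = c(d, d),
               censored = "none"))
  }
  if (sm[1] > criterion) {
    return(new("ThresholdEstimate", value = dose[1], criterion = criterion,
               scale = scale, method = method,
               bracket = c(dose[1], dose[1]), censored = "left"))
  }
  if (max(sm) < criterion) {
    stop(errorCondition(
      sprintf("detection never reaches the %.2f criterion (max smoothed proportion %.3f)",
              criterion, max(sm)),
      maxProportion = max(sm),
      class = c("pyrasense_no_crossing", "pyrasense_error")))
  }
  j <- which(sm > criterion)[1]
  i <- j - 1L
  t <- (criterion - sm[i]) / (sm[j] - sm[i])
  value <- 10^(log10(dose[i]) + t * (log10(dose[j]) - log10(dose[i])))
  new("ThresholdEstimate", value = value, criterion = criterion,
      scale = scale, method = method, bracket = c(dose[i], dose[j]),
      censored = "none")
}

#' Estimate a group odor threshold from an ascending detection curve
#'
#' Proportions on the chosen scale (raw proportion-correct by default, or
#' Abbott chance-corrected detection) are first made non-decreasing by
#' pool-adjacent-violators smoothing weighted by panel size, then the
#' threshold is read off by linear interpolation on log-dose between the
#' doses bracketing the criterion. A dose hitting the criterion exactly is
#' returned as-is; a curve already above the criterion at the lowest dose
#' yields a left-censored estimate (threshold at most that dose); a curve
#' that never reaches the criterion raises a `pyrasense_no_crossing`
#' error carrying the maximum smoothed proportion.
#'
#' The default applies the 50% criterion to raw proportion-correct, the
#' literal group-threshold reading; `scale = "chance_corrected"` applies
#' it to detection probability (i.e. 66.7% correct in a 3-AFC task),
#' which targets the psychometric midpoint. The choice is recorded in the
#' returned object.
#'
#' @param curve a [DetectionCurve-class].
#' @param criterion probability in (0, 1); default 0.5.
#' @param scale `"raw_correct"` (default) or `"chance_corrected"`.
#' @return a [ThresholdEstimate-class].
#' @export
#' @examples
#' cur <- DetectionCurve(c(0.1, 0.2), n = 20, k = c(8, 12))
#' estimateThreshold(cur)
estimateThreshold <- function(curve, criterion = 0.5,
                              scale = c("raw_correct", "chance_corrected")) {
  scale <- match.arg(scale)
  if (criterion <= 0 || criterion >= 1)
    .err("criterion must be in (0, 1)", "pyrasense_design_error")
  prop <- if (scale == "raw_correct") pCorrect(curve) else pDetect(curve)
  .thresholdFromProportions(doses(curve), prop, nPanelists(curve),
                            criterion, scale,
                            "log-linear interpolation (PAVA-smoothed)")
}

#' Maximum-likelihood psychometric fit with a guessing floor
#'
#' Fits `p_correct(d) = chance + (1 - chance) / (1 + exp(-slope *
#' (log10 d - midpoint)))` — a logistic in log10-dose with the guessing
#' floor fixed at `chance` and no lapse — by binomial maximum likelihood.
#' The fitted threshold is the dose at the psychometric midpoint, where
#' detection is 50% and expected proportion-correct is `(1 + chance)/2`.
#'
#' Chance-level data (pooled proportion at or below chance) and fully
#' non-detected/saturated curves are not identifiable and raise a
#' `pyrasense_fit_error`; perfectly separated step data drive the slope
#' to the optimizer bound and are returned with `boundary = TRUE` and a
#' warning.
#'
#' @param curve a [DetectionCurve-class] with at least 3 doses.
#' @param slopeInit initial slope (per log10-dose unit).
#' @return list with `midpoint` (log10 dose), `slope`, `threshold`
#'   (`10^midpoint`), `logLik` and `boundary`.
#' @export
fitPsychometric <- function(curve, slopeInit = 4.9) {
  x <- log10(doses(curve)); n <- nPanelists(curve); k <- nCorrect(curve)
  chance <- curve@chance
  if (length(x) < 3L)
    .err("need at least 3 doses", "pyrasense_design_error")
  if (sum(k) / sum(n) <= chance + 1e-9)
    stop(errorCondition("responses are at chance level at all doses; midpoint not identifiable",
                        class = c("pyrasense_fit_error", "pyrasense_error")))
  if (all(k == n))
    stop(errorCondition("detection saturated at all doses; midpoint not identifiable",
                        class = c("pyrasense_fit_error", "pyrasense_error")))
  nll <- function(par) {
    p <- chance + (1 - chance) * plogis(exp(par[2]) * (x - par[1]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(dbinom(k, n, p, log = TRUE))
  }
  # midpoint init: where chance-corrected detection first exceeds 0.5
  pd <- abbottCorrect(k / n, chance)
  m0 <- if (any(pd >= 0.5)) x[which(pd >= 0.5)[1]] else max(x)
  fit <- optim(c(m0, log(slopeInit)), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  slope <- exp(fit$par[2])
  boundary <- slope > 50
  if (boundary) {
    warning("slope at optimizer boundary (separated step data); midpoint is the step location",
            call. = FALSE)
  }
  list(midpoint = fit$par[1], slope = slope, threshold = 10^fit$par[1],
       logLik = -fit$value, boundary = boundary)
}
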
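# Feller additive (independence) model for joint odor detection and the
# synergy / additive / suppression verdict.

#' Feller additive-model prediction for joint detection
#'
#' Probability of detecting a mixture when its two components are
#' detected independently: `p(AB) = p(A) + p(B) - p(A) p(B)`, i.e.
#' `1 - p(AB) = (1 - p(A)) (1 - p(B))`. Commutative; never below either
#' component. All arguments must be on the chance-corrected detection
#' scale — treating raw forced-choice proportions as independent would
#' double-count guessing.
#'
#' @param pA,pB detection probabilities in `[0, 1]` (vectorized with
#'   recycling).
#' @return predicted mixture detection probability.
#' @export
#' @examples
#' fellerPredict(0.3, 0.4)  # 0.58
fellerPredict <- function(pA, pB) {
  .assertProb(pA, "p(A)"); .assertProb(pB, "p(B)")
  pA + pB - pA * pB
}

#' Ratio between a reference and a test odor threshold
#'
#' `reference / test`, reported at one decimal: the factor by which the
#' threshold decreased from reference to test condition.
#'
#' @param reference,test thresholds in the same dose units, > 0.
#' @return the ratio (full precision; round with [roundHalfUp()] for
#'   display).
#' @export
#' @examples
#' thresholdRatio(0.456, 0.143)  # 3.19 -> prints as 3.2
thresholdRatio <- function(reference, test) {
  if (any(reference <= 0) || any(test <= 0))
    .err("thresholds must be > 0", "pyrasense_domain_error")
  reference / test
}

# Studentized deviation statistic for the interaction exponent,
# vectorized over bootstrap resamples (kB/kAB are doses x resamples
# matrices). Writing the mixture complement as Fbar = (1 - pA)(1 - pB),
# the package's synergy index theta enters as
# p(AB) = 1 - Fbar^theta (theta = 1 is Feller additivity). The statistic
# is the GLS projection of the per-dose residuals (observed - predicted
# proportion correct) onto the template one doubling of theta would
# produce, (1 - chance) * Fbar * (1 - Fbar), using the full residual
# covariance: mixture binomial variance, propagated component-B
# variance and, in measured mode, the rank-one term from the shared
# component-A estimate (inverted by Sherman-Morrison). Detection
# estimates enter through the unclipped linear Abbott transform, which
# keeps the plug-in prediction unbiased near chance; clipped values are
# for reporting only. Approximately N(0, 1) under additivity.
.interactionScore <- function(kAB, kB, kA, nAB, nB, nA, measured, chance) {
  B <- ncol(kB); D <- nrow(kB)
  pA <- if (measured) (kA / nA - chance) / (1 - chance) else rep(0, B)
  pAm <- matrix(pA, D, B, byrow = TRUE)
  pBdet <- (kB / nB - chance) / (1 - chance)
  pred <- chance + (1 - chance) * (pAm + pBdet - pAm * pBdet)
  fbar <- pmin(pmax((1 - pAm) * (1 - pBdet), 0), 1)
  s <- (1 - chance) * fbar * (1 - fbar)
  pgB <- (kB + 0.5) / (nB + 1)
  pgAB <- pmin(pmax(pred, 0.02), 0.98)
  V <- pgAB * (1 - pgAB) / nAB + (1 - pAm)^2 * pgB * (1 - pgB) / nB
  w <- 1 / V
  if (measured) {
    pgA <- (kA + 0.5) / (nA + 1)
    vA <- pgA * (1 - pgA) / nA
    cc <- 1 - pBdet
    shrink <- vA / (1 + vA * colSums(w * cc^2))
    corr <- matrix(shrink * colSums(w * cc * s), D, B, byrow = TRUE)
    a <- w * s - corr * w * cc
  } else {
    a <- w * s
  }
  den <- sqrt(pmax(colSums(s * a), 1e-12))
  colSums(a * (kAB / nAB - pred)) / den
}

# Equal-tail bootstrap p-values of one dataset against its own fitted
# additive null (Jeffreys-shrunken plug-in; the whole estimation
# pipeline is replayed on each resample).
.interactionTails <- function(kAB0, kB0, kA0, nAB, nB, nA, measured,
                              chance, nBoot) {
  D <- length(kB0)
  tObs <- .interactionScore(matrix(kAB0), matrix(kB0), kA0, nAB, nB, nA,
                            measured, chance)
  pcB <- (kB0 + 0.5) / (nB + 1)
  pcA <- if (measured) (kA0 + 0.5) / (nA + 1) else 0
  pAd <- max((pcA - chance) / (1 - chance), 0)
  pBd <- pmax((pcB - chance) / (1 - chance), 0)
  predGen <- chance + (1 - chance) * (pAd + pBd - pAd * pBd)
  kBs <- matrix(rbinom(D * nBoot, nB, pcB), D)
  kAs <- if (measured) rbinom(nBoot, nA, pcA) else 0
  kABs <- matrix(rbinom(D * nBoot, nAB, predGen), D)
  tStar <- .interactionScore(kABs, kBs, kAs, nAB, nB, nA, measured, chance)
  c(pU = (1 + sum(tStar >= tObs)) / (nBoot + 1),
    pL = (1 + sum(tStar <= tObs)) / (nBoot + 1),
    stat = tObs)
}

#' Classify a perceptual interaction against the Feller additive model
#'
#' Computes the dose-wise Feller prediction for the mixture from the
#' component curves (component A enters as a single dose-independent
#' detection probability), estimates group thresholds on both the
#' observed and predicted curves, and calls the interaction:
#'
#' * `synergy` — observed detection significantly above the additive
#'   prediction (equivalently, observed threshold below predicted);
#' * `suppression` — significantly below;
#' * `additive` — no significant deviation.
#'
#' The decision statistic is the studentized score for the package's
#' interaction exponent (`p(AB) = 1 - ((1-p(A))(1-p(B)))^theta`, additive
#' null `theta = 1`), which pools the per-dose deviations from the
#' prediction along the direction a genuine synergy/suppression would
#' move them while accounting for the sampling noise of the component
#' estimates. Its equal-tail p-value against a parametric bootstrap of
#' the fitted additive model (all counts regenerated, the estimation
#' pipeline replayed per resample) is then itself calibrated by a double
#' bootstrap: `nOuter` datasets are drawn from the fitted null, each gets
#' its own inner-bootstrap p-value, and the observed p-value's rank among
#' them is the reported `pValue` — this removes the first-order level
#' error a plug-in bootstrap carries at panel sizes around 20. A
#' significant result is called synergy or suppression only when the
#' threshold ordering points the same way (synergy means detecting the
#' mixture at lower doses than independence predicts). Per-dose
#' exact-binomial comparisons of the observed mixture counts against the
#' predicted proportion-correct are reported as descriptive detail in
#' `doseTests` — taken alone they ignore the sampling error of the
#' component estimates, which is why the call does not use them.
#'
#' @param pair a [MixturePair-class].
#' @param pAMode `"measured"` (estimate p(A) from the pooled component-A
#'   counts via Abbott correction; at/below chance gives 0) or `"zero"`
#'   (assume the fixed bundle alone is undetectable). Must be chosen
#'   explicitly: the two modes answer different questions.
#' @param alpha decision level (default 0.05).
#' @param criterion,scale threshold settings passed to the same
#'   estimator as [estimateThreshold()].
#' @param nBoot inner bootstrap resamples per p-value (default 299).
#' @param nOuter outer (calibration) datasets for the double bootstrap
#'   (default 499).
#' @param seed optional seed for the bootstrap (caller's RNG stream is
#'   preserved).
#' @return an [InteractionVerdict-class].
#' @export
classifyInteraction <- function(pair, pAMode = c("measured", "zero"),
                                alpha = 0.05, criterion = 0.5,
                                scale = c("raw_correct", "chance_corrected"),
                                nBoot = 299, nOuter = 499, seed = NULL) {
  pAMode <- match.arg(pAMode)
  scale <- match.arg(scale)
  measured <- pAMode == "measured"
  B <- pair@componentB; AB <- pair@mixture
  if (length(B) < 3L)
    .err("need at least 3 doses with data", "pyrasense_design_error")
  chance <- B@chance
  if (measured && !length(pair@componentA))
    .err("pAMode = 'measured' requires component A counts",
         "pyrasense_design_error")
  pA <- if (measured)
    abbottCorrect(pair@componentA$k / pair@componentA$n, chance) else 0

  pBdet <- pDetect(B)
  predDet <- fellerPredict(pA, pBdet)
  predCorrect <- abbottInverse(predDet, chance)

  # per-dose exact binomial detail (descriptive; see Details)
  kAB <- nCorrect(AB); nAB <- nPanelists(AB)[1]
  pUp <- pbinom(kAB - 1, nAB, predCorrect, lower.tail = FALSE)
  pDown <- pbinom(kAB, nAB, predCorrect)
  doseTests <- data.frame(
    dose = doses(B), n = nAB, k = kAB,
    observed_correct = kAB / nAB, predicted_correct = predCorrect,
    p_upper = pUp, p_lower = pDown,
    p_two_sided = pmin(1, 2 * pmin(pUp, pDown)))

  kB <- nCorrect(B); nB <- nPanelists(B)[1]
  nA <- if (length(pair@componentA)) pair@componentA$n else 0L
  kA <- if (nA > 0) pair@componentA$k else 0L
  D <- length(kB)

  db <- .withSeed(seed, {
    obs <- .interactionTails(kAB, kB, kA, nAB, nB, nA, measured, chance,
                             nBoot)
    p2obs <- min(1, 2 * min(obs[c("pU", "pL")]))
    # outer calibration datasets from the fitted additive null
    pcB0 <- (kB + 0.5) / (nB + 1)
    pcA0 <- if (nA > 0) (kA + 0.5) / (nA + 1) else 0
    pAd <- max((pcA0 - chance) / (1 - chance), 0)
    pBd <- pmax((pcB0 - chance) / (1 - chance), 0)
    predGen0 <- chance + (1 - chance) * (pAd + pBd - pAd * pBd)
    p2out <- vapply(seq_len(nOuter), function(j) {
      kBj <- rbinom(D, nB, pcB0)
      kAj <- if (measured) rbinom(1, nA, pcA0) else 0L
      kABj <- rbinom(D, nAB, predGen0)
      tj <- .interactionTails(kABj, kBj, kAj, nAB, nB, nA, measured,
                              chance, nBoot)
      min(1, 2 * min(tj[c("pU", "pL")]))
    }, numeric(1))
    list(obs = obs, p2obs = p2obs,
         pAdj = (1 + sum(p2out <= p2obs)) / (nOuter + 1))
  })
  pValue <- db$pAdj
  obsStat <- unname(db$obs["stat"])

  rightCensored <- function(expr) {
    tryCatch(expr, pyrasense_no_crossing = function(e) {
      new("ThresholdEstimate", value = NA_real_, criterion = criterion,
          scale = scale, method = "none (criterion never reached)",
          bracket = c(NA_real_, NA_real_), censored = "right")
    })
  }
  thrObs <- rightCensored(
    estimateThreshold(AB, criterion = criterion, scale = scale))
  predProp <- if (scale == "raw_correct") predCorrect else predDet
  thrPred <- rightCensored(.thresholdFromProportions(
    doses(B), predProp, rep(nAB, D), criterion, scale,
    "log-linear interpolation (PAVA-smoothed, Feller-predicted curve)"))
  ratio <- thrPred@value / thrObs@value

  # the call requires the calibrated statistic and the threshold
  # ordering to agree: a significant deviation whose threshold
  # comparison points the other way is not called
  call <- if (pValue < alpha) {
    if (db$obs["pU"] < db$obs["pL"]) "synergy" else "suppression"
  } else "additive"
  if (is.finite(ratio)) {
    if (call == "synergy" && ratio < 1) call <- "additive"
    if (call == "suppression" && ratio > 1) call <- "additive"
  }

  predicted <- data.frame(
    dose = doses(B), p_b_detect = pBdet, predicted_detect = predDet,
    predicted_correct = predCorrect,
    observed_detect = pDetect(AB), observed_correct = kAB / nAB)

  new("InteractionVerdict", call = call, ratio = ratio,
      thresholdObserved = thrObs, thresholdPredicted = thrPred,
      predicted = predicted, doseTests = doseTests, pValue = pValue,
      statistic = obsStat, alpha = alpha, pA = pA,
      settings = list(pAMode = pAMode, scale = scale,
                      criterion = criterion, nBoot = nBoot,
                      nOuter = nOuter, seed = seed))
}
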
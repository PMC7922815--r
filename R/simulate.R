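# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with the statistical structure the analysis assumes:
# a latent roasted-aroma intensity driving between-sample concentration
# variation, per-panelist logistic psychometric detection with a 1/3
# guessing floor, and mixtures whose joint detection follows or deviates
# from Feller independence by a tunable factor theta.

#' Study configuration for the synthetic generators
#'
#' Defaults mirror the published study design: 11 Baijiu samples, panels
#' of 20 (thresholds) judging ascending factor-2 series, 16 pyrazines
#' with the published mean concentrations and odor thresholds, latent
#' roasted-aroma intensity uniform on \[1, 6.3\], psychometric slope 4.9
#' per log10-dose (10-90% span of about three dilution steps), panelist
#' threshold heterogeneity of one dilution step (geometric sd), and an
#' interaction factor theta of 1 (Feller-exact mixtures; theta > 1
#' synergy, theta < 1 suppression).
#'
#' @param nSamples number of Baijiu samples.
#' @param nPanelists panelists per 3-AFC dose.
#' @param compounds compound ids; defaults to the 16 profiled pyrazines.
#' @param baseConcentration named mean concentrations (ug/L); defaults to
#'   the published across-sample means.
#' @param loadings named latent-intensity loadings on the log10
#'   concentration scale (0 = null compound).
#' @param noiseSd residual sd of log10 concentration (default 0.15,
#'   roughly 40% CV between brands).
#' @param latentRange range of the latent 0-7 intensity.
#' @param slope psychometric slope per log10-dose.
#' @param panelistGsd sd of individual log10 thresholds (log10(2) = one
#'   dilution step; 0 disables heterogeneity for oracle tests).
#' @param chance guessing probability.
#' @param theta mixture interaction factor.
#' @param pA true detection probability of the fixed sub-threshold bundle
#'   in mixture experiments. The default 0.15 is the value consistent
#'   with the published shift of the additive-model threshold (0.456 to
#'   0.292 mL) under the default slope.
#' @param seed optional integer seed stored with the config.
#' @return a validated list of class `"pyrasense_config"`.
#' @export
studyConfig <- function(nSamples = 11, nPanelists = 20,
                        compounds = NULL, baseConcentration = NULL,
                        loadings = NULL, noiseSd = 0.15,
                        latentRange = c(1, 6.3), slope = 4.9,
                        panelistGsd = log10(2), chance = 1/3,
                        theta = 1, pA = 0.15, seed = NULL) {
  if (is.null(compounds)) {
    compounds <- if (!is.null(baseConcentration)) names(baseConcentration)
                 else if (!is.null(loadings)) names(loadings)
                 else .defaultCompounds$compound
  }
  if (is.null(baseConcentration)) {
    defaults <- setNames(.defaultCompounds$mean_concentration,
                         .defaultCompounds$compound)
    unknown <- setdiff(compounds, names(defaults))
    if (length(unknown))
      stop("no default base concentration for: ",
           paste(unknown, collapse = ", "))
    baseConcentration <- defaults[compounds]
  }
  full <- setNames(rep(0, length(compounds)), compounds)
  if (!is.null(loadings)) full[names(loadings)] <- loadings
  loadings <- full
  stopifnot(nSamples >= 2, nPanelists >= 1, theta > 0, noiseSd >= 0,
            slope > 0, panelistGsd >= 0, chance > 0, chance < 1,
            pA >= 0, pA <= 1, all(baseConcentration > 0))
  structure(list(nSamples = nSamples, nPanelists = nPanelists,
                 compounds = compounds,
                 baseConcentration = baseConcentration,
                 loadings = loadings, noiseSd = noiseSd,
                 latentRange = latentRange, slope = slope,
                 panelistGsd = panelistGsd, chance = chance,
                 theta = theta, pA = pA, seed = seed),
            class = "pyrasense_config")
}

# published across-sample mean concentrations (ug/L) used as generator
# baselines so synthetic tables have realistic magnitudes
.defaultCompounds <- data.frame(
  compound = c("Pyrazine", "2M", "26DM", "TM2YM", "23DM", "2356TTM",
               "235TM", "2A3M", "2E6M", "2E3M", "2E35DM", "5E23DM",
               "26DE", "23DE", "23DE5M", "2I3M"),
  mean_concentration = c(119.82, 103.79, 1013.61, 28.82, 264.59, 1077.62,
                         856.38, 125.13, 399.10, 13.72, 248.11, 3.33,
                         30.96, 112.91, 6.99, 2.77))

#' Loading that yields a target latent correlation
#'
#' For log10 concentration = loading * z(latent) + noise, the Pearson
#' correlation with the latent is `loading / sqrt(loading^2 + noiseSd^2)`;
#' this inverts that relation (rank correlation is slightly attenuated).
#'
#' @param r target correlation in (0, 1).
#' @param noiseSd residual sd (log10 scale).
#' @return the loading.
#' @export
loadingForCorrelation <- function(r, noiseSd = 0.15) {
  stopifnot(r > 0, r < 1)
  noiseSd * r / sqrt(1 - r^2)
}

#' Simulate a samples-by-compounds concentration table
#'
#' Draws a latent roasted-aroma intensity per sample (uniform on the
#' configured range of the 0-7 scale) and, per compound, log10
#' concentrations `log10(base) + loading * z(latent) + noise`, where
#' `z(latent)` is the standardized latent. Compounds with loading 0 are
#' null controls for the Spearman screen.
#'
#' @param cfg a [studyConfig()].
#' @param seed optional seed (overrides `cfg$seed`).
#' @return list with `concentration` (compounds-by-samples matrix,
#'   ug/L), `intensity` (named latent intensity per sample) and
#'   `loadings` (ground truth).
#' @export
simulateConcentrationTable <- function(cfg = studyConfig(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  .withSeed(seed, {
    samples <- sprintf("S%02d", seq_len(cfg$nSamples))
    latent <- runif(cfg$nSamples, cfg$latentRange[1], cfg$latentRange[2])
    z <- (latent - mean(cfg$latentRange)) /
      (diff(cfg$latentRange) / sqrt(12))
    conc <- vapply(cfg$compounds, function(cp) {
      lg <- log10(cfg$baseConcentration[[cp]]) + cfg$loadings[[cp]] * z +
        rnorm(cfg$nSamples, 0, cfg$noiseSd)
      10^lg
    }, numeric(cfg$nSamples))
    list(concentration = t(conc)[, , drop = FALSE] |>
           `dimnames<-`(list(cfg$compounds, samples)),
         intensity = setNames(latent, samples),
         loadings = cfg$loadings)
  })
}

#' Simulate panel ratings around a latent intensity
#'
#' Convenience generator for descriptive-panel tables: each assessor x
#' replicate score is the sample's latent intensity plus Gaussian rating
#' noise, clipped to the 0-7 scale.
#'
#' @param intensity named per-sample latent intensity (0-7).
#' @param nAssessors,nReplicates panel design (defaults 12 x 3).
#' @param ratingSd rating noise sd in scale points.
#' @param attribute attribute label.
#' @param seed optional seed.
#' @return long rating data.frame (assessor, replicate, sample,
#'   attribute, score).
#' @export
simulateRatings <- function(intensity, nAssessors = 12, nReplicates = 3,
                            ratingSd = 0.8, attribute = "roasted",
                            seed = NULL) {
  .withSeed(seed, {
    grid <- expand.grid(assessor = sprintf("A%02d", seq_len(nAssessors)),
                        replicate = seq_len(nReplicates),
                        sample = names(intensity),
                        stringsAsFactors = FALSE)
    grid$attribute <- attribute
    grid$score <- pmin(pmax(
      intensity[grid$sample] + rnorm(nrow(grid), 0, ratingSd), 0), 7)
    grid
  })
}

# per-panelist detection probabilities at log10-dose x: logistic around
# individual thresholds ti
.panelDetect <- function(x, ti, slope) {
  plogis(slope * outer(ti, x, function(t, d) d - t))
}

#' Simulate ascending 3-AFC responses
#'
#' Each panelist carries an individual threshold drawn log-normally
#' around the group threshold (geometric sd `panelistGsd`; 0 gives a
#' homogeneous panel) and detects dose `d` with probability
#' `plogis(slope * (log10 d - log10 t_i))`; a response is correct with
#' probability `chance + (1 - chance) * p_detect`. Responses are
#' independent across doses given the individual thresholds.
#'
#' @param series dose vector (e.g. from [makeGeometricSeries()]).
#' @param groupThreshold group (median) threshold in dose units.
#' @param cfg a [studyConfig()] supplying panel size, slope,
#'   heterogeneity and chance.
#' @param seed optional seed.
#' @return a [DetectionCurve-class].
#' @export
simulateAfcResponses <- function(series, groupThreshold,
                                 cfg = studyConfig(), seed = NULL) {
  stopifnot(groupThreshold > 0)
  .withSeed(seed, {
    x <- log10(series)
    ti <- rnorm(cfg$nPanelists, log10(groupThreshold), cfg$panelistGsd)
    pDet <- .panelDetect(x, ti, cfg$slope)
    pCor <- cfg$chance + (1 - cfg$chance) * pDet
    k <- colSums(matrix(rbinom(length(pCor), 1, pCor), nrow(pCor)))
    DetectionCurve(series, n = cfg$nPanelists, k = k, chance = cfg$chance)
  })
}

#' Simulate a component/mixture 3-AFC experiment
#'
#' Component B (the dose-varying supra-threshold bundle) follows the
#' psychometric model of [simulateAfcResponses()]; the fixed
#' sub-threshold bundle A is detected with constant probability
#' `cfg$pA` and judged once per ascending session (its pooled counts
#' therefore span `nPanelists * length(series)` judgements); the true
#' mixture detection is
#' `1 - ((1 - pA) (1 - pB))^theta`, so `theta = 1` reproduces Feller
#' independence exactly, `theta > 1` yields synergy and `theta < 1`
#' suppression. A-alone counts (one fixed-composition 3-AFC test) are
#' generated too.
#'
#' @inheritParams simulateAfcResponses
#' @return a [MixturePair-class].
#' @export
simulateMixtureExperiment <- function(series, groupThreshold,
                                      cfg = studyConfig(), seed = NULL) {
  stopifnot(groupThreshold > 0)
  .withSeed(seed, {
    x <- log10(series)
    n <- cfg$nPanelists; ch <- cfg$chance
    tiB <- rnorm(n, log10(groupThreshold), cfg$panelistGsd)
    pB <- .panelDetect(x, tiB, cfg$slope)
    kB <- colSums(matrix(rbinom(length(pB), 1, ch + (1 - ch) * pB),
                         nrow(pB)))
    tiM <- rnorm(n, log10(groupThreshold), cfg$panelistGsd)
    pBm <- .panelDetect(x, tiM, cfg$slope)
    pABtrue <- 1 - ((1 - cfg$pA) * (1 - pBm))^cfg$theta
    kAB <- colSums(matrix(rbinom(length(pABtrue), 1,
                                 ch + (1 - ch) * pABtrue), nrow(pABtrue)))
    # the fixed bundle A is judged once per ascending session, so its
    # pooled counts accumulate across the dose steps
    kA <- sum(rbinom(length(series), n, ch + (1 - ch) * cfg$pA))
    MixturePair(
      componentB = DetectionCurve(series, n, kB, ch),
      mixture = DetectionCurve(series, n, kAB, ch),
      componentA = list(n = n * length(series), k = kA))
  })
}

#' Simulate a calibration series
#'
#' Response ratios `slope * conc + intercept + N(0, noiseSd)` around a
#' constant internal-standard response, reproducible from the seed.
#'
#' @param slope,intercept true line (response ratio per ug/L; ratio).
#' @param noiseSd Gaussian ratio noise sd.
#' @param concentrations calibration levels (ug/L), >= 2 values.
#' @param isResponse internal-standard response (area units).
#' @param seed optional seed.
#' @return data.frame with `concentration`, `analyte`,
#'   `internalStandard` and `ratio`.
#' @export
simulateCalibration <- function(slope, intercept = 0, noiseSd = 0,
                                concentrations = c(1, 5, 10, 50, 100,
                                                   500, 1000),
                                isResponse = 1e5, seed = NULL) {
  stopifnot(slope > 0, length(concentrations) >= 2)
  .withSeed(seed, {
    ratio <- slope * concentrations + intercept +
      rnorm(length(concentrations), 0, noiseSd)
    data.frame(concentration = concentrations,
               analyte = ratio * isResponse,
               internalStandard = isResponse,
               ratio = ratio)
  })
}
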
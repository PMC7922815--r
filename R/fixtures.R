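# Loaders for the packaged plain-text fixtures: the published SSAB
# concentration/threshold tables, the spike designs, the interaction dose
# ladder and the MRM acquisition metadata.

.extdata <- function(name) {
  f <- system.file("extdata", name, package = "pyrasense", mustWork = TRUE)
  f
}

#' The published SSAB pyrazine profile as an AromaExperiment
#'
#' Sixteen pyrazines quantified in eleven commercial soy sauce aroma type
#' Baijiu samples (mean of triplicates, ug/L, with replicate RSDs) plus
#' their odor thresholds in 53% ethanol/water. Thresholds were measured
#' in ethanol solution, not Baijiu, so [oav()] warns about the matrix
#' mismatch — that caveat is real and inherited from the source data.
#'
#' @return an [AromaExperiment-class] (16 compounds x 11 samples).
#' @export
#' @examples
#' ae <- ssabExperiment()
#' suppressWarnings(head(oavProfile(ae)))
ssabExperiment <- function() {
  conc <- readConcentrationTable(.extdata("ssab_concentrations.tsv"))
  thr <- readThresholdTable(.extdata("ssab_thresholds.tsv"))
  AromaExperiment(conc, thr, rsd = attr(conc, "rsd"),
                  sampleMatrix = "SSAB")
}

#' Spike-test design for the olfactory-impact experiments
#'
#' The ten 3-AFC addition tests: which of the eight pyrazines were spiked
#' into the low-roasted-aroma sample, at the listed concentrations, and
#' the published significance outcome.
#'
#' @return list with `design` (test x compound presence grid plus
#'   outcome code) and `concentrations` (compound, concentration ug/L).
#' @export
spikeDesign <- function() {
  list(design = .readDelim(.extdata("spike_design.tsv")),
       concentrations = .readDelim(.extdata("spike_concentrations.tsv")))
}

#' Dose ladder of the interaction experiments
#'
#' The printed ascending volume series (mL of stock into 15 mL matrix),
#' factor 2 per step. Supplied verbatim as data: its low-end printed
#' values are rounded inconsistently, so it is not regenerated.
#'
#' @return numeric dose vector (mL).
#' @export
interactionDoses <- function() .readDelim(.extdata("interaction_design.tsv"))$dose_mL

#' Stock concentrations of the interaction-bundle pyrazines
#'
#' @return data.frame with `compound`, `stock_concentration` (ug/L) and
#'   `role` (supra/sub-threshold bundle membership).
#' @export
pyrazineStocks <- function() .readDelim(.extdata("pyrazine_stocks.tsv"))

#' MRM acquisition parameters (metadata fixture)
#'
#' Retention times and MRM transitions of the 16 pyrazines and the
#' internal standard. Reference metadata only — the package performs no
#' chromatography.
#'
#' @return data.frame.
#' @export
mrmParameters <- function() .readDelim(.extdata("mrm_parameters.tsv"))

#' Convert a stock volume to an in-glass concentration
#'
#' Thresholds from volume-dosed experiments are kept in volume units
#' (mL of stock into `matrixVolume` mL matrix); this optional conversion
#' assumes additive volumes: `c = stock * v / (v + matrixVolume)`.
#'
#' @param volume dosed stock volume (mL).
#' @param stockConcentration stock concentration (ug/L).
#' @param matrixVolume matrix volume (mL), default 15.
#' @return concentration in the glass (ug/L).
#' @export
doseToConcentration <- function(volume, stockConcentration,
                                matrixVolume = 15) {
  stockConcentration * volume / (volume + matrixVolume)
}
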
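# Odor activity value profiling on an AromaExperiment.

#' Construct an AromaExperiment
#'
#' @param concentration compounds-by-samples numeric matrix (ug/L; NA for
#'   missing). Row names are compound ids, column names sample ids.
#' @param thresholds data.frame with columns `compound`, `threshold`
#'   (ug/L) and optionally `matrix`, `source`; one row per compound of
#'   `concentration`.
#' @param rsd optional matrix of replicate RSDs (%), same dimensions.
#' @param sampleMatrix label of the matrix the samples live in (used to
#'   warn when OAVs are computed against thresholds measured in a
#'   different matrix). Default `"unspecified"`.
#' @return an [AromaExperiment-class].
#' @export
#' @examples
#' conc <- matrix(c(100, 40), 2, 1,
#'                dimnames = list(c("a", "b"), "S1"))
#' thr <- data.frame(compound = c("a", "b"), threshold = c(50, 80))
#' ae <- AromaExperiment(conc, thr)
#' oav(ae)
AromaExperiment <- function(concentration, thresholds, rsd = NULL,
                            sampleMatrix = "unspecified") {
  concentration <- as.matrix(concentration)
  if (is.null(rownames(concentration)))
    .err("concentration matrix needs compound row names",
         "pyrasense_data_error")
  idx <- match(rownames(concentration), thresholds$compound)
  if (anyNA(idx))
    .err(sprintf("no threshold for compound(s): %s",
                 paste(rownames(concentration)[is.na(idx)], collapse = ", ")),
         "pyrasense_data_error")
  thresholds <- thresholds[idx, , drop = FALSE]
  rd <- DataFrame(
    threshold = thresholds$threshold,
    matrix = if ("matrix" %in% names(thresholds)) thresholds$matrix
             else "unspecified",
    source = if ("source" %in% names(thresholds)) thresholds$source
             else "unspecified",
    row.names = rownames(concentration))
  assays <- list(concentration = concentration)
  if (!is.null(rsd)) assays$rsd <- as.matrix(rsd)
  cd <- DataFrame(sampleMatrix = rep(sampleMatrix, ncol(concentration)),
                  row.names = colnames(concentration))
  se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd)
  new("AromaExperiment", se)
}

#' @describeIn AromaExperiment per-compound odor thresholds (named,
#'   ug/L).
#' @param x an `AromaExperiment`.
#' @param ... unused.
#' @export
setMethod("odorThresholds", "AromaExperiment", function(x, ...)
  setNames(rowData(x)$threshold, rownames(x)))

#' Odor activity value
#'
#' OAV = concentration / odor threshold. The matrix method divides each
#' compound row of the concentration assay by its threshold and warns when
#' thresholds were measured in a different matrix than the samples
#' (ethanol-solution thresholds applied to Baijiu, say) — the ratio is
#' still computed, the caveat is the user's to weigh.
#'
#' @param x an [AromaExperiment-class], or numeric concentration(s).
#' @param threshold odor threshold(s) (ug/L, > 0) for the numeric method.
#' @param ... unused.
#' @return numeric OAV(s) / a compounds-by-samples OAV matrix.
#' @export
#' @examples
#' oav(521.57, 7.5)
setMethod("oav", "numeric", function(x, threshold, ...) {
  if (any(threshold <= 0))
    .err("odor threshold must be > 0", "pyrasense_data_error")
  if (any(x < 0, na.rm = TRUE))
    .err("concentration must be >= 0", "pyrasense_data_error")
  x / threshold
})

#' @rdname oav
#' @export
setMethod("oav", "AromaExperiment", function(x, ...) {
  thrMat <- unique(rowData(x)$matrix)
  smpMat <- unique(colData(x)$sampleMatrix)
  foreign <- setdiff(thrMat, smpMat)
  if (length(foreign) && !identical(smpMat, "unspecified")) {
    warning(sprintf(
      "OAVs use thresholds measured in '%s' for samples in '%s'",
      paste(foreign, collapse = "/"), paste(smpMat, collapse = "/")),
      call. = FALSE)
  }
  sweep(assay(x, "concentration"), 1, rowData(x)$threshold, "/")
})

#' Alias for the scalar OAV
#'
#' Convenience wrapper around the numeric [oav()] method.
#'
#' @param concentration concentration (ug/L).
#' @param threshold odor threshold (ug/L, > 0).
#' @return concentration / threshold.
#' @export
computeOAV <- function(concentration, threshold) oav(concentration, threshold)

#' Band an OAV as negligible, sub- or supra-threshold
#'
#' OAV < 0.1 is negligible; 0.1 <= OAV < 1 is sub-threshold; OAV >= 1 is
#' supra-threshold (an OAV of exactly 1 counts as supra-threshold — the
#' compound has reached its threshold).
#'
#' @param x numeric OAV(s), >= 0 (NA passes through).
#' @param ... unused.
#' @return character vector of bands.
#' @export
#' @examples
#' classifyOAV(c(0.05, 0.19, 1, 40))
classifyOAV <- function(x, ...) {
  if (any(x < 0, na.rm = TRUE))
    .err("OAV must be >= 0", "pyrasense_domain_error")
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok & x < 0.1] <- "negligible"
  out[ok & x >= 0.1 & x < 1] <- "sub_threshold"
  out[ok & x >= 1] <- "supra_threshold"
  out
}

#' @describeIn AromaExperiment band matrix from [classifyOAV()] applied
#'   to the OAV matrix.
#' @export
setMethod("oavBands", "AromaExperiment", function(x, ...) {
  o <- oav(x)
  matrix(classifyOAV(as.vector(o)), nrow(o), ncol(o), dimnames = dimnames(o))
})

#' Concentration as a percentage of the odor threshold
#'
#' `round(100 * concentration / threshold)` to the nearest integer,
#' rounding half up. Note one published value was truncated instead
#' (80/172 = 46.5% printed as 46%); this function returns 47 there.
#'
#' @param concentration concentration(s), ug/L.
#' @param threshold odor threshold(s), ug/L, > 0.
#' @return integer percentage(s).
#' @export
#' @examples
#' percentOfThreshold(180, 965)  # 19
percentOfThreshold <- function(concentration, threshold) {
  if (any(threshold <= 0))
    .err("odor threshold must be > 0", "pyrasense_data_error")
  roundHalfUp(100 * concentration / threshold)
}

#' Summarize a per-sample value vector
#'
#' Minimum, maximum and mean across samples, ignoring missing entries
#' (missing never counts as zero).
#'
#' @param values numeric vector (one value per sample).
#' @return named numeric `c(min =, max =, mean =)`.
#' @export
summarizeCompound <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    .err("no non-missing values to summarize", "pyrasense_data_error")
  c(min = min(values), max = max(values), mean = mean(values))
}

#' @describeIn AromaExperiment per-compound min/max/mean of the
#'   concentration or OAV matrix, as a data.frame.
#' @param what `"concentration"` or `"oav"`.
#' @export
setMethod("compoundSummary", "AromaExperiment",
          function(x, what = c("concentration", "oav"), ...) {
  what <- match.arg(what)
  m <- if (what == "oav") suppressWarnings(oav(x))
       else assay(x, "concentration")
  s <- t(apply(m, 1, summarizeCompound))
  data.frame(compound = rownames(m), min = s[, "min"], max = s[, "max"],
             mean = s[, "mean"], row.names = NULL)
})

#' @describeIn AromaExperiment tidy per-(sample, compound) OAV table with
#'   columns sample, compound, concentration, threshold, oav, band.
#' @export
setMethod("oavProfile", "AromaExperiment", function(x, ...) {
  conc <- assay(x, "concentration")
  o <- suppressWarnings(oav(x))
  df <- data.frame(
    sample = rep(colnames(conc), each = nrow(conc)),
    compound = rep(rownames(conc), ncol(conc)),
    concentration = as.vector(conc),
    threshold = rep(rowData(x)$threshold, ncol(conc)),
    oav = as.vector(o),
    band = classifyOAV(as.vector(o)))
  df[!is.na(df$concentration), , drop = FALSE]
})

#' @describeIn AromaExperiment compounds whose mean-across-samples
#'   concentration reaches the odor threshold (OAV of the sample mean
#'   >= 1) — the aroma contributors in the published sense. Individual
#'   samples may push other compounds over threshold; see [oavBands()].
#' @export
setMethod("contributingCompounds", "AromaExperiment", function(x, ...) {
  conc <- assay(x, "concentration")
  meanConc <- rowMeans(conc, na.rm = TRUE)
  names(which(meanConc / rowData(x)$threshold >= 1))
})
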
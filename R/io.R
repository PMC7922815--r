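# Delimited-text readers/writers for the pipeline's table schemas.
# CSV or TSV is picked by file extension; all readers validate the
# documented headers and return plain structures or package classes.

.readDelim <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  read.delim(file, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE)
}

.needCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .err(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")),
         "pyrasense_schema_error")
  invisible(df)
}

#' Read a long-format concentration table
#'
#' Expects columns `compound`, `sample`, `concentration` and optionally
#' `rsd_percent`.
#'
#' @param file path to a CSV/TSV file.
#' @return compounds-by-samples concentration matrix; when present, the
#'   RSD matrix is attached as attribute `"rsd"`.
#' @export
readConcentrationTable <- function(file) {
  df <- .needCols(.readDelim(file), c("compound", "sample", "concentration"),
                  "concentration table")
  if (any(df$concentration < 0, na.rm = TRUE))
    .err("concentrations must be >= 0", "pyrasense_data_error")
  compounds <- unique(df$compound); samples <- unique(df$sample)
  if (anyDuplicated(df[c("compound", "sample")]))
    .err("duplicate compound x sample entries", "pyrasense_data_error")
  toMat <- function(col) {
    m <- matrix(NA_real_, length(compounds), length(samples),
                dimnames = list(compounds, samples))
    m[cbind(match(df$compound, compounds), match(df$sample, samples))] <-
      df[[col]]
    m
  }
  conc <- toMat("concentration")
  if ("rsd_percent" %in% names(df)) attr(conc, "rsd") <- toMat("rsd_percent")
  conc
}

#' Read an odor-threshold table
#'
#' Expects columns `compound`, `threshold` and optionally `matrix`,
#' `source`.
#'
#' @param file path to a CSV/TSV file.
#' @return data.frame, one row per compound.
#' @export
readThresholdTable <- function(file) {
  df <- .needCols(.readDelim(file), c("compound", "threshold"),
                  "threshold table")
  if (anyDuplicated(df$compound))
    .err("one threshold entry per compound, please", "pyrasense_data_error")
  if (any(!is.finite(df$threshold) | df$threshold <= 0))
    .err("thresholds must be finite and > 0", "pyrasense_data_error")
  df
}

#' Read a descriptive-panel rating table
#'
#' Long format with columns `assessor`, `replicate`, `sample`,
#' `attribute`, `score` (0-7); duplicate assessor x replicate x sample x
#' attribute rows are rejected.
#'
#' @param file path to a CSV/TSV file.
#' @return the validated data.frame.
#' @export
readRatingTable <- function(file) {
  df <- .needCols(.readDelim(file),
                  c("assessor", "replicate", "sample", "attribute", "score"),
                  "rating table")
  if (any(df$score < 0 | df$score > 7))
    .err("scores must lie on the 0-7 scale", "pyrasense_data_error")
  if (anyDuplicated(df[c("assessor", "replicate", "sample", "attribute")]))
    .err("duplicate assessor x replicate x sample x attribute rows",
         "pyrasense_data_error")
  df
}

#' Read a forced-choice trial table
#'
#' Columns `label`, `n`, `k` (optionally `chance`).
#'
#' @param file path to a CSV/TSV file.
#' @return the validated data.frame.
#' @export
readTrialTable <- function(file) {
  df <- .needCols(.readDelim(file), c("label", "n", "k"), "trial table")
  if (any(df$k < 0 | df$k > df$n))
    .err("counts must satisfy 0 <= k <= n", "pyrasense_data_error")
  df
}

#' Read a mixture-experiment table
#'
#' Long format with columns `component` (A, B or AB), `dose`, `n`, `k`.
#' Component A rows are pooled into the fixed-bundle counts; B and AB
#' must share an identical dose axis.
#'
#' @param file path to a CSV/TSV file.
#' @param chance guessing probability.
#' @return a [MixturePair-class].
#' @export
readMixtureTable <- function(file, chance = 1/3) {
  df <- .needCols(.readDelim(file), c("component", "dose", "n", "k"),
                  "mixture table")
  get <- function(comp) {
    sub <- df[df$component == comp, , drop = FALSE]
    sub[order(sub$dose), , drop = FALSE]
  }
  b <- get("B"); ab <- get("AB"); a <- get("A")
  if (!nrow(b) || !nrow(ab))
    .err("mixture table needs both B and AB components",
         "pyrasense_schema_error")
  MixturePair(
    componentB = DetectionCurve(b$dose, b$n, b$k, chance),
    mixture = DetectionCurve(ab$dose, ab$n, ab$k, chance),
    componentA = if (nrow(a)) list(n = sum(a$n), k = sum(a$k)) else NULL)
}

#' Write a tidy table as TSV
#'
#' @param df data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a report object as JSON
#'
#' @param x a list.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeReport <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}
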
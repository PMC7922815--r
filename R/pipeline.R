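# File-level orchestration: each runner reads the configured tables,
# executes one analysis stage and writes a tidy TSV plus a JSON report
# that embeds every analysis choice, the seed, a config fingerprint and
# the package version, so results are self-describing.

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    .err("config must be a list or the path to a YAML file",
         "pyrasense_config_error")
  config
}

.requireKeys <- function(config, keys) {
  missing <- setdiff(keys, names(config))
  if (length(missing))
    .err(sprintf("config is missing key(s): %s",
                 paste(missing, collapse = ", ")),
         "pyrasense_config_error")
  invisible(config)
}

.reportStamp <- function(config) {
  list(package_version = as.character(packageVersion("pyrasense")),
       config_hash = .configHash(config),
       seed = if (is.null(config$seed)) NA else config$seed)
}

.outPath <- function(config, name) {
  dir <- config$out_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the OAV profiling stage over files
#'
#' Reads a concentration table and a threshold table, builds an
#' [AromaExperiment-class], and writes the tidy OAV profile
#' (`oav_profile.tsv`, OAVs rounded to 1 decimal alongside the full
#' precision value) plus a JSON summary of per-compound concentration
#' and OAV ranges and the contributing compounds.
#'
#' @param config list or YAML path with keys `concentrations`,
#'   `thresholds`, optional `out_dir`, `sample_matrix`, `seed`.
#' @return invisibly, a list with the profile, the summaries and the
#'   written paths.
#' @export
runOav <- function(config) {
  config <- .requireKeys(.loadConfig(config),
                         c("concentrations", "thresholds"))
  conc <- readConcentrationTable(config$concentrations)
  thr <- readThresholdTable(config$thresholds)
  ae <- AromaExperiment(conc, thr, rsd = attr(conc, "rsd"),
                        sampleMatrix = config$sample_matrix %||% "unspecified")
  if (nrow(ae) == 0)
    .err("empty compound set", "pyrasense_config_error")
  profile <- oavProfile(ae)
  profile$oav_1dp <- roundHalfUp(profile$oav, 1)
  message(sprintf("OAV profile: %d compounds x %d samples (%d records)",
                  nrow(ae), ncol(ae), nrow(profile)))
  tsv <- .outPath(config, "oav_profile.tsv")
  writeTsv(profile, tsv)
  concSummary <- compoundSummary(ae, "concentration")
  oavSummary <- compoundSummary(ae, "oav")
  report <- c(.reportStamp(config), list(
    n_compounds = nrow(ae), n_samples = ncol(ae),
    contributing_compounds = as.list(contributingCompounds(ae)),
    concentration_ranges = concSummary,
    oav_ranges = data.frame(oavSummary[1],
                            roundHalfUp(oavSummary[-1], 1))))
  json <- .outPath(config, "oav_summary.json")
  writeReport(report, json)
  invisible(list(experiment = ae, profile = profile,
                 summary = report, files = c(tsv, json)))
}

#' Run the sensory-correlation screen over files
#'
#' Reads a long rating table and a concentration table, aggregates the
#' attribute intensity per sample, runs the omnibus one-way ANOVA and
#' the directional Spearman screen, and writes the correlation table,
#' the flagged-compound edge list and a JSON report logging the decision
#' thresholds used.
#'
#' @param config list or YAML path with keys `ratings`,
#'   `concentrations`, optional `attribute` (default `"roasted"`),
#'   `rho_min`, `alpha`, `adjust`, `out_dir`, `seed`.
#' @return invisibly, a list with the profile, screen results and
#'   written paths.
#' @export
runScreen <- function(config) {
  config <- .requireKeys(.loadConfig(config),
                         c("ratings", "concentrations"))
  attribute <- config$attribute %||% "roasted"
  ratings <- readRatingTable(config$ratings)
  conc <- readConcentrationTable(config$concentrations)
  profile <- aggregateIntensity(ratings, attribute)
  attr(profile, "attribute") <- attribute
  omnibus <- anovaBySample(ratings, attribute)
  screen <- spearmanScreen(conc, profile,
                           rhoMin = config$rho_min %||% 0.5,
                           alpha = config$alpha %||% 0.05,
                           adjust = config$adjust %||% "none")
  message(sprintf(
    "screen: %d compounds over %d samples; rho > %g, one-sided p < %g -> %d flagged",
    nrow(screen), attr(screen, "n_samples"), config$rho_min %||% 0.5,
    config$alpha %||% 0.05, sum(screen$significant)))
  tsv <- .outPath(config, "screen.tsv")
  writeTsv(screen, tsv)
  edges <- .outPath(config, "edges.tsv")
  writeTsv(attr(screen, "edges"), edges)
  report <- c(.reportStamp(config), list(
    attribute = attribute, rho_min = config$rho_min %||% 0.5,
    alpha = config$alpha %||% 0.05, adjust = config$adjust %||% "none",
    n_samples = attr(screen, "n_samples"),
    anova = as.list(omnibus),
    intensity = profile,
    flagged = as.list(screen$compound[screen$significant])))
  json <- .outPath(config, "screen.json")
  writeReport(report, json)
  invisible(list(intensity = profile, anova = omnibus, screen = screen,
                 files = c(tsv, edges, json)))
}

#' Run the threshold + Feller interaction stage over files
#'
#' Reads a mixture trial table (components A/B/AB), classifies the
#' interaction against the Feller additive model and writes a JSON
#' verdict (thresholds, ratio, call, per-dose detail) plus a per-dose
#' TSV. Censored curves are reported with explicit flags rather than
#' errors.
#'
#' @param config list or YAML path with keys `mixture` (trial table
#'   path) and `pa_mode` (`"measured"` or `"zero"` — must be explicit),
#'   optional `scale`, `criterion`, `alpha`, `n_boot`, `n_outer`,
#'   `out_dir`, `seed`.
#' @return invisibly, a list with the verdict and written paths.
#' @export
runInteraction <- function(config) {
  config <- .requireKeys(.loadConfig(config), c("mixture", "pa_mode"))
  pair <- readMixtureTable(config$mixture)
  verdict <- classifyInteraction(
    pair, pAMode = config$pa_mode,
    alpha = config$alpha %||% 0.05,
    criterion = config$criterion %||% 0.5,
    scale = config$scale %||% "raw_correct",
    nBoot = config$n_boot %||% 299,
    nOuter = config$n_outer %||% 499,
    seed = config$seed)
  thrO <- verdict@thresholdObserved; thrP <- verdict@thresholdPredicted
  if (is.finite(verdict@ratio)) {
    message(sprintf(
      "odor threshold %.3f vs additive prediction %.3f: decreased by a factor of %.1f (%s)",
      thrO@value, thrP@value, roundHalfUp(verdict@ratio, 1), verdict@call))
  } else {
    message("threshold censored on at least one curve; see flags in report")
  }
  tsv <- .outPath(config, "interaction_doses.tsv")
  writeTsv(merge(verdict@predicted, verdict@doseTests), tsv)
  report <- c(.reportStamp(config), list(
    call = verdict@call,
    p_value = verdict@pValue,
    statistic = verdict@statistic,
    alpha = verdict@alpha,
    p_a = verdict@pA,
    settings = verdict@settings[c("pAMode", "scale", "criterion", "nBoot",
                                  "nOuter")],
    threshold_observed = list(value = thrO@value, censored = thrO@censored,
                              bracket = thrO@bracket),
    threshold_predicted = list(value = thrP@value, censored = thrP@censored,
                               bracket = thrP@bracket),
    ratio = verdict@ratio,
    ratio_1dp = roundHalfUp(verdict@ratio, 1),
    dose_detail = verdict@doseTests))
  json <- .outPath(config, "interaction.json")
  writeReport(report, json)
  invisible(list(verdict = verdict, files = c(tsv, json)))
}
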
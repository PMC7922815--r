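# Exact 3-AFC discrimination testing and Abbott chance correction.

#' Exact binomial p-value for a forced-choice test
#'
#' Upper-tail probability `P(X >= k | n, chance)` of observing at least
#' `k` correct choices among `n` panelists when everyone guesses (chance
#' = 1/3 for 3-AFC). Exact binomial; no normal approximation.
#'
#' @param k correct choices, `0 <= k <= n`.
#' @param n panelists.
#' @param chance guessing probability in (0, 1).
#' @return p-value in (0, 1].
#' @export
#' @examples
#' afcPvalue(12, 20)
afcPvalue <- function(k, n, chance = 1/3) {
  if (any(k < 0 | k > n)) .err("need 0 <= k <= n", "pyrasense_domain_error")
  if (any(chance <= 0 | chance >= 1))
    .err("chance must be in (0, 1)", "pyrasense_domain_error")
  pbinom(k - 1, n, chance, lower.tail = FALSE)
}

#' Significance code for a p-value
#'
#' The ladder used in discrimination-test tables: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p p-value(s) in (0, 1].
#' @return character code(s).
#' @export
#' @examples
#' significanceCode(c(0.0005, 0.009, 0.03, 0.2))
significanceCode <- function(p) {
  .assertProb(p, "p-value")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

#' Abbott chance correction
#'
#' Converts forced-choice proportion-correct into the underlying
#' detection probability: `p_d = (p_c - chance) / (1 - chance)`, clipped
#' below at 0 (an observed proportion under chance carries no evidence of
#' detection).
#'
#' @param pCorrect observed proportion(s) correct in `[0, 1]`.
#' @param chance guessing probability (1/3 for 3-AFC).
#' @return detection probability in `[0, 1]`.
#' @seealso [abbottInverse()]
#' @export
#' @examples
#' abbottCorrect(2/3)  # 0.5
abbottCorrect <- function(pCorrect, chance = 1/3) {
  .assertProb(pCorrect, "proportion correct")
  pmax((pCorrect - chance) / (1 - chance), 0)
}

#' Inverse Abbott correction
#'
#' Maps a detection probability back to the expected proportion correct:
#' `p_c = chance + (1 - chance) * p_d`.
#'
#' @param pDetect detection probability in `[0, 1]`.
#' @param chance guessing probability.
#' @return expected proportion correct in `[chance, 1]`.
#' @export
abbottInverse <- function(pDetect, chance = 1/3) {
  .assertProb(pDetect, "detection probability")
  chance + (1 - chance) * pDetect
}

#' Evaluate a table of forced-choice tests
#'
#' @param trials data.frame with columns `label`, `n`, `k` (and
#'   optionally `chance`).
#' @param chance guessing probability used when the table has no
#'   `chance` column.
#' @return the table plus `p_correct`, `p_value`, `code` and
#'   `detection_probability` columns.
#' @export
afcTestTable <- function(trials, chance = 1/3) {
  if (!all(c("label", "n", "k") %in% names(trials)))
    .err("trial table needs columns label, n, k", "pyrasense_data_error")
  ch <- if ("chance" %in% names(trials)) trials$chance else chance
  p <- afcPvalue(trials$k, trials$n, ch)
  data.frame(trials,
             p_correct = trials$k / trials$n,
             p_value = p,
             code = significanceCode(p),
             detection_probability = abbottCorrect(trials$k / trials$n, ch))
}
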
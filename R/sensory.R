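# Descriptive-panel aggregation and the Spearman concentration-vs-aroma
# screen.

#' Aggregate panel ratings into a per-sample intensity profile
#'
#' Mean and sample standard deviation of the 0-7 intensity scores over
#' assessors and replicates, per sample.
#'
#' @param ratings long data.frame with columns `assessor`, `replicate`,
#'   `sample`, `attribute`, `score`.
#' @param attribute attribute label to profile (e.g. `"roasted"`).
#' @return data.frame with columns `sample`, `mean`, `sd`, `n`.
#' @export
aggregateIntensity <- function(ratings, attribute) {
  need <- c("assessor", "replicate", "sample", "attribute", "score")
  if (!all(need %in% names(ratings)))
    .err(sprintf("rating table needs columns: %s", paste(need, collapse = ", ")),
         "pyrasense_data_error")
  if (any(ratings$score < 0 | ratings$score > 7))
    .err("scores must lie on the 0-7 scale", "pyrasense_data_error")
  sub <- ratings[ratings$attribute == attribute, , drop = FALSE]
  if (!nrow(sub))
    .err(sprintf("no ratings for attribute '%s'", attribute),
         "pyrasense_data_error")
  groups <- split(sub$score, sub$sample)
  data.frame(
    sample = names(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(g) if (length(g) > 1) sd(g) else NA_real_,
                numeric(1)),
    n = lengths(groups), row.names = NULL)
}

#' One-way ANOVA of panel scores across samples
#'
#' Fixed-effect one-way analysis of variance of the attribute scores with
#' sample as the grouping factor (the omnibus test behind intensity
#' profiles; post-hoc letter displays are out of scope).
#'
#' @inheritParams aggregateIntensity
#' @return named numeric `c(F =, p =, df1 =, df2 =)`.
#' @export
anovaBySample <- function(ratings, attribute) {
  sub <- ratings[ratings$attribute == attribute, , drop = FALSE]
  if (!nrow(sub))
    .err(sprintf("no ratings for attribute '%s'", attribute),
         "pyrasense_data_error")
  counts <- table(sub$sample)
  if (length(counts) < 2L)
    .err("need at least 2 samples", "pyrasense_design_error")
  if (any(counts < 2L))
    .err("need at least 2 ratings per sample", "pyrasense_design_error")
  withinVar <- vapply(split(sub$score, sub$sample), var, numeric(1))
  if (all(withinVar == 0))
    .err("zero within-group variance: F is degenerate",
         "pyrasense_degenerate_variance")
  fit <- aov(score ~ factor(sample), data = sub)
  tab <- summary(fit)[[1]]
  c(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
    df1 = tab$Df[1], df2 = tab$Df[2])
}

# all permutations of 1..n (n! x n matrix); n <= 9 keeps this tractable
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Spearman rho (Pearson on mid-ranks) with exact permutation p for n <= 9
# and the t approximation beyond. Returns rho plus one-sided (positive)
# and two-sided p-values.
.spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, pOne = NA_real_, pTwo = NA_real_,
                degenerate = TRUE))
  }
  rho <- cor(rx, ry)
  n <- length(x)
  if (n <= 9L) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    # each row permutes ry: rhoPerm_i = cor(rx, ry[perm_i])
    rhoPerm <- as.vector(matrix(ry[perms], nrow(perms)) %*% rxc) / denom
    pOne <- mean(rhoPerm >= rho - 1e-12)
    pTwo <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    pOne <- pt(tt, n - 2, lower.tail = FALSE)
    pTwo <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, pOne = pOne, pTwo = min(pTwo, 1), degenerate = FALSE)
}

#' Screen compound concentrations for rank correlation with an attribute
#'
#' Spearman's rho (Pearson correlation of mid-ranks, so ties average)
#' between each compound's per-sample concentration and the per-sample
#' attribute intensity. A compound is flagged when `rho > rhoMin` and the
#' one-sided (positive-association) p-value is below `alpha` — the screen
#' is directional: only positive relationships are called, negative
#' correlations are reported but never flagged. P-values are exact
#' permutation for n <= 9 common samples and the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` beyond; both one- and two-sided
#' values are reported. No multiple-testing correction by default;
#' `adjust = "BH"` applies Benjamini-Hochberg to the one-sided p-values
#' (noted in a message).
#'
#' @param conc compounds-by-samples concentration matrix or an
#'   [AromaExperiment-class].
#' @param intensity per-sample intensity: a named numeric vector or the
#'   data.frame from [aggregateIntensity()].
#' @param rhoMin minimum rho to flag (default 0.5).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame (one row per compound) with `rho`, `p_one_sided`,
#'   `p_two_sided`, `significant`, `degenerate`; the flagged compounds'
#'   weighted edge list (attribute-compound, weight rho) is attached as
#'   attribute `"edges"`.
#' @export
spearmanScreen <- function(conc, intensity, rhoMin = 0.5, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is(conc, "AromaExperiment")) conc <- assay(conc, "concentration")
  if (is.data.frame(intensity)) {
    attrLabel <- attr(intensity, "attribute")
    intensity <- setNames(intensity$mean, intensity$sample)
  } else attrLabel <- NULL
  if (is.null(attrLabel)) attrLabel <- "intensity"
  common <- intersect(colnames(conc), names(intensity))
  if (length(common) < 4L)
    .err("need at least 4 common samples between tables",
         "pyrasense_insufficient_data")
  conc <- conc[, common, drop = FALSE]
  intensity <- intensity[common]
  res <- lapply(rownames(conc), function(cp)
    .spearman(conc[cp, ], intensity))
  pOne <- vapply(res, `[[`, numeric(1), "pOne")
  pAdj <- if (adjust == "BH") {
    message("Benjamini-Hochberg adjustment applied to one-sided p-values")
    stats::p.adjust(pOne, method = "BH")
  } else pOne
  out <- data.frame(
    compound = rownames(conc),
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_one_sided = pOne,
    p_two_sided = vapply(res, `[[`, numeric(1), "pTwo"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"))
  out$significant <- !out$degenerate & !is.na(out$rho) &
    out$rho > rhoMin & pAdj < alpha
  sig <- out[out$significant, , drop = FALSE]
  attr(out, "edges") <- data.frame(attribute = rep(attrLabel, nrow(sig)),
                                   compound = sig$compound,
                                   weight = sig$rho)
  attr(out, "n_samples") <- length(common)
  out
}
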
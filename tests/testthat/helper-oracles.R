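# Independent oracles used to freeze expected values: deliberately
# brute-force / closed-form, sharing no code with the implementation.

# upper-tail binomial probability by term-by-term enumeration
bruteBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  js <- k:n
  sum(choose(n, js) * p^js * (1 - p)^(n - js))
}

# closed-form OLS slope/intercept from sums
olsClosed <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# exact permutation p-values for Spearman rho by full enumeration
permSpearmanOracle <- function(x, y) {
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  perms <- NULL
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(gen(seq_len(n)),
                 function(p) cor(rank(x), rank(y)[p]), numeric(1))
  list(rho = rho,
       pOne = mean(rhos >= rho - 1e-12),
       pTwo = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# simple mixture pair built from fixed counts
makePair <- function(dose, kB, kAB, n = 20, kA = NULL, nA = NULL) {
  MixturePair(
    componentB = DetectionCurve(dose, n, kB),
    mixture = DetectionCurve(dose, n, kAB),
    componentA = if (!is.null(kA)) list(n = nA, k = kA) else NULL)
}
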
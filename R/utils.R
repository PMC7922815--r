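# Shared numeric helpers and condition constructors.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; the published tables round half up
#' (e.g. an OAV of 0.125 prints as 0.13 at 2 dp). Used by every reporting
#' layer in the package.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(c(0.125, 2.5, -2.5), c(2, 0, 0))
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# classed error so callers can distinguish validation failures from R errors
.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pyrasense_error")))
}

.assertProb <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    .err(sprintf("%s must lie in [0, 1]", what), "pyrasense_domain_error")
  }
  invisible(x)
}

# Weighted pool-adjacent-violators: least-squares isotonic (non-decreasing)
# regression. Stack formulation; weights are typically panelist counts.
.pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1L) return(y)
  vals <- numeric(0); wts <- numeric(0); counts <- integer(0)
  for (i in seq_len(n)) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); counts <- c(counts, 1L)
    m <- length(vals)
    while (m > 1L && vals[m - 1L] > vals[m]) {
      wNew <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- (vals[m - 1L] * wts[m - 1L] + vals[m] * wts[m]) / wNew
      wts[m - 1L] <- wNew
      counts[m - 1L] <- counts[m - 1L] + counts[m]
      vals <- vals[-m]; wts <- wts[-m]; counts <- counts[-m]
      m <- m - 1L
    }
  }
  rep(vals, counts)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# djb2 string hash over the deparsed config; enough to fingerprint a run
# in reports (not cryptographic).
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2^31
  sprintf("%08x", h)
}
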
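#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef vcov model.matrix pnorm qnorm plogis qlogis
#'   quantile rnorm rbinom rgamma runif rlnorm pchisq pf pt sd lm glm
#'   quasibinomial gaussian residuals as.formula setNames complete.cases
#'   predict weighted.mean
#' @importFrom utils read.csv write.csv
NULL

fail <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fail("`%s` must be a single finite number", name)
  if (strict && x <= lower) fail("`%s` must be > %g", name, lower)
  if (!strict && x < lower) fail("`%s` must be >= %g", name, lower)
  invisible(x)
}

#' Weighted quantiles by cumulative-weight interpolation
#'
#' Computes quantiles of `x` under sampling weights `w` by linear
#' interpolation of the empirical weighted CDF evaluated at the
#' (Hajek-normalised) midpoint positions.  With equal weights this matches
#' `quantile(x, probs, type = 7)` up to interpolation convention at small n
#' and converges to it as n grows.
#'
#' @param x numeric vector.
#' @param w positive weights, recycled to `length(x)`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- is.finite(x) & is.finite(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) fail("no finite values for weighted quantile")
  if (any(w <= 0)) fail("weights must be positive")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  # plotting positions: (cw - w/2) / sum(w), standard weighted-CDF midpoints
  pp <- (cw - w / 2) / sum(w)
  sapply(probs, function(p) {
    if (p <= pp[1L]) return(x[1L])
    if (p >= pp[length(pp)]) return(x[length(x)])
    stats::approx(pp, x, xout = p, ties = "ordered")$y
  })
}

#' Weighted median with an even-split convention
#'
#' Returns the smallest observed value whose cumulative normalised weight
#' reaches 1/2; when the cumulative weight hits 1/2 exactly at an
#' observation, the midpoint between that observation and the next distinct
#' value is returned (so equal weights on values 1..4 give 2.5).
#'
#' @param x numeric vector.
#' @param w positive weights (default equal).
#' @return scalar cutpoint.
#' @export
weighted_median <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- is.finite(x) & is.finite(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) fail("no finite values for weighted median")
  if (any(w <= 0)) fail("weights must be positive")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  j <- which(cw >= 0.5 - 1e-12)[1L]
  if (abs(cw[j] - 0.5) < 1e-12 && j < length(x)) (x[j] + x[j + 1L]) / 2 else x[j]
}

# Joint Wald chi-square test of coef[idx] = 0 using a supplied covariance.
wald_test <- function(beta, V, idx) {
  b <- beta[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(Vi, b))
  df <- length(idx)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Deterministic per-variable sub-stream seed so adding a variable to the
# generator does not perturb draws of earlier variables.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  set.seed(substream_seed(seed, name))
  expr
}
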
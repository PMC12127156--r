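#' Default restricted-cubic-spline knot locations
#'
#' Places knots at the conventional quantiles for k = 3, 4, or 5 knots
#' (k = 3: 10/50/90; k = 4: 5/35/65/95; k = 5: 5/27.5/50/72.5/95 percent),
#' survey-weighted when weights are supplied.
#'
#' @param x exposure values.
#' @param k number of knots (3, 4, or 5).
#' @param weights optional survey weights.
#' @return numeric vector of strictly increasing knots.
#' @export
rcs_knots <- function(x, k = 4, weights = NULL) {
  if (!k %in% 3:5) fail("k must be 3, 4 or 5")
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  kn <- if (is.null(weights)) quantile(x, probs, type = 7, names = FALSE)
        else weighted_quantile(x, weights, probs)
  if (any(diff(kn) <= 0)) fail("degenerate knots: quantiles are not distinct")
  kn
}

#' Restricted cubic spline basis
#'
#' Natural cubic spline basis in the truncated-power construction normalised
#' by the squared boundary-knot span: column 1 is the linear term x; columns
#' 2..k-1 are the nonlinear terms, each zero below the first knot (the basis
#' is linear in both tails) and twice continuously differentiable at every
#' knot.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot vector of length 3-5, interior to
#'   the finite range of `x` when `check_range` is TRUE.
#' @param check_range verify the knots lie within `range(x)`.
#' @return matrix with `length(knots) - 1` columns and attribute `"knots"`.
#' @export
rcs_basis <- function(x, knots, check_range = TRUE) {
  k <- length(knots)
  if (!k %in% 3:5) fail("need 3-5 knots")
  if (any(diff(knots) <= 0)) fail("knots must be strictly increasing (no duplicates)")
  if (check_range) {
    fin <- range(x[is.finite(x)])
    if (knots[1] < fin[1] || knots[k] > fin[2])
      fail("knots must lie within the data range")
  }
  cube <- function(u) pmax(u, 0)^3
  span2 <- (knots[k] - knots[1])^2
  B <- matrix(NA_real_, length(x), k - 1L,
              dimnames = list(NULL, paste0("rcs", seq_len(k - 1L))))
  B[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    B[, j + 1L] <- (cube(x - tj) -
      cube(x - knots[k - 1L]) * (knots[k] - tj) / (knots[k] - knots[k - 1L]) +
      cube(x - knots[k]) * (knots[k - 1L] - tj) / (knots[k] - knots[k - 1L])) /
      span2
  }
  structure(B, knots = knots)
}

#' Restricted cubic spline dose-response (survey-weighted logistic)
#'
#' Fits a survey-weighted logistic model of a binary outcome on the RCS
#' basis of a continuous exposure plus covariates, and reports a joint Wald
#' test of all spline terms (`p_overall`: any association) and of the
#' nonlinear terms only (`p_nonlinear`: departure from log-linearity),
#' together with a dose-response curve of log-odds differences (and
#' pointwise CIs) centred at a reference exposure value (default the
#' weighted median).
#'
#' @param outcome name of the 0/1 outcome column.
#' @param exposure name of the continuous exposure column.
#' @param covariates character vector of adjustment columns (may be empty).
#' @param data data.frame.
#' @param design a [survey_design()].
#' @param k number of knots (default 4) when `knots` is NULL.
#' @param knots explicit knot vector (overrides `k`).
#' @param grid_n number of grid points for the curve.
#' @param ref reference exposure value (default: weighted median).
#' @param level confidence level.
#' @return object of class `rcs_result`: `knots`, `p_overall`, `p_nonlinear`,
#'   `curve` (data.frame exposure/log_odds/conf_low/conf_high, odds-ratio
#'   columns), `fit`, `vcov`, `ref`.
#' @export
rcs_logistic <- function(outcome, exposure, covariates = character(), data,
                         design, k = 4, knots = NULL, grid_n = 100,
                         ref = NULL, level = 0.95) {
  used <- c(outcome, exposure, covariates)
  miss <- setdiff(used, names(data))
  if (length(miss)) fail("column(s) not in data: %s", paste(miss, collapse = ", "))
  keep <- complete.cases(data[, used, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  design <- design_subset(design, keep)
  x <- data[[exposure]]
  if (is.null(knots)) knots <- rcs_knots(x, k, design$weights)
  B <- rcs_basis(x, knots)
  df <- data.frame(.y = data[[outcome]], B,
                   data[, covariates, drop = FALSE], check.names = FALSE)
  fml <- as.formula(paste(".y ~", paste(c(colnames(B), covariates), collapse = " + ")))
  mfit <- fit_weighted_glm(fml, df, design, level = level)
  V <- mfit$vcov
  b <- coef(mfit$fit)
  spl <- match(colnames(B), names(b))
  nl <- spl[-1L]
  p_overall <- wald_test(b, V, spl)$p_value
  p_nonlinear <- if (length(nl)) wald_test(b, V, nl)$p_value else NA_real_
  if (is.null(ref)) ref <- weighted_median(x, design$weights)
  grid <- seq(min(x), max(x), length.out = grid_n)
  D <- rcs_basis(grid, knots, check_range = FALSE) -
    matrix(rcs_basis(ref, knots, check_range = FALSE), grid_n,
           length(spl), byrow = TRUE)
  eta <- drop(D %*% b[spl])
  se <- sqrt(pmax(rowSums((D %*% V[spl, spl]) * D), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  curve <- data.frame(exposure = grid, log_odds = eta,
                      conf_low = eta - zq * se, conf_high = eta + zq * se,
                      or = exp(eta), or_low = exp(eta - zq * se),
                      or_high = exp(eta + zq * se))
  structure(list(knots = knots, p_overall = p_overall,
                 p_nonlinear = p_nonlinear, curve = curve, fit = mfit$fit,
                 vcov = V, ref = ref, n = mfit$n),
            class = "rcs_result")
}

#' @export
print.rcs_result <- function(x, ...) {
  cat(sprintf("RCS logistic dose-response: %d knots at %s\n",
              length(x$knots), paste(signif(x$knots, 4), collapse = ", ")))
  cat(sprintf("p (overall) = %.4g, p (nonlinear) = %.4g, n = %d\n",
              x$p_overall, x$p_nonlinear, x$n))
  invisible(x)
}
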
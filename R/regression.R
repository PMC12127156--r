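#' Design-based robust covariance for a fitted model
#'
#' In `weights_only_robust` mode this is the HC0 sandwich (with survey
#' weights entering through the model's prior weights); in `taylor` mode the
#' score contributions are summed within PSUs and a stratified between-PSU
#' covariance is used (with-replacement approximation).
#'
#' @param fit a `glm`/`lm` object fitted with the design weights.
#' @param design a [survey_design()] aligned with the model frame rows.
#' @return covariance matrix of the coefficients.
#' @export
vcov_design <- function(fit, design) {
  if (design$variance_mode != "taylor") return(sandwich::vcovHC(fit, type = "HC0"))
  ef <- sandwich::estfun(fit)
  B <- sandwich::bread(fit) / stats::nobs(fit)
  meat <- matrix(0, ncol(ef), ncol(ef))
  for (h in unique(design$strata)) {
    ih <- which(design$strata == h)
    S <- rowsum(ef[ih, , drop = FALSE], group = design$psu[ih])
    nh <- nrow(S)
    if (nh < 2L) next
    Sc <- sweep(S, 2, colMeans(S))
    meat <- meat + nh / (nh - 1) * crossprod(Sc)
  }
  V <- B %*% meat %*% B
  dimnames(V) <- dimnames(sandwich::vcovHC(fit, type = "HC0"))
  V
}

coef_table <- function(fit, V, exponentiate, level = 0.95) {
  b <- coef(fit)
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  zq <- qnorm(1 - (1 - level) / 2)
  lo <- b - zq * se
  hi <- b + zq * se
  out <- data.frame(term = names(b), estimate = b, se = se,
                    conf_low = lo, conf_high = hi, p_value = p,
                    row.names = NULL)
  if (exponentiate) {
    out$or <- exp(b)
    out$or_low <- exp(lo)
    out$or_high <- exp(hi)
  }
  out
}

svy_fit <- function(formula, data, design, family) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- complete.cases(mf)
  if (!all(keep)) {
    data <- data[keep, , drop = FALSE]
    design <- design_subset(design, keep)
  }
  if (length(design$weights) != nrow(data))
    fail("design weights must align with the model rows")
  env <- new.env(parent = environment(formula))
  assign(".w", design$weights, envir = env)
  environment(formula) <- env
  fit <- glm(formula, data = data, family = family, weights = .w)
  if (!fit$converged) fail("model did not converge")
  mu <- fit$fitted.values
  separation <- fit$family$family %in% c("binomial", "quasibinomial") &&
    any(mu < 1e-8 | mu > 1 - 1e-8)
  list(fit = fit, design = design, separation = separation)
}

#' Survey-weighted binomial logistic regression
#'
#' Weighted maximum likelihood (iteratively reweighted least squares with the
#' survey weights as prior weights; the quasi-binomial family is used so
#' non-integer weighted responses are accepted — coefficients are identical
#' to the binomial fit), robust sandwich or Taylor-linearized standard
#' errors, Wald confidence intervals, and exponentiated (odds-ratio)
#' estimates.  Perfect separation is detected (any fitted probability within
#' 1e-8 of 0/1) and reported, never silently ignored.
#'
#' @param formula model formula; the outcome must be 0/1.
#' @param data data.frame.
#' @param design a [survey_design()] aligned with `data` rows.
#' @param level confidence level (default 0.95).
#' @return object of class `svy_glm_fit`: `coefficients` (tidy table with
#'   `or` columns), `fit`, `vcov`, `n`, `separation`, `scale = "odds_ratio"`.
#' @export
fit_weighted_glm <- function(formula, data, design, level = 0.95) {
  yname <- all.vars(formula)[1L]
  yv <- data[[yname]]
  if (!all(yv[!is.na(yv)] %in% c(0, 1)))
    fail("outcome `%s` must be binary 0/1 for the binomial family", yname)
  r <- svy_fit(formula, data, design, quasibinomial())
  if (r$separation)
    warning("possible perfect separation: fitted probabilities at 0/1 boundary")
  V <- vcov_design(r$fit, r$design)
  structure(list(coefficients = coef_table(r$fit, V, TRUE, level),
                 fit = r$fit, vcov = V, n = stats::nobs(r$fit),
                 separation = r$separation, scale = "odds_ratio"),
            class = "svy_glm_fit")
}

#' Survey-weighted linear regression
#'
#' Weighted least squares with robust design-based standard errors; with
#' equal weights the coefficients are exactly ordinary least squares.
#'
#' @inheritParams fit_weighted_glm
#' @return object of class `svy_lm_fit` (as [fit_weighted_glm()] but `scale
#'   = "beta"`, no `or` columns).
#' @export
fit_weighted_lm <- function(formula, data, design, level = 0.95) {
  r <- svy_fit(formula, data, design, gaussian())
  qrf <- r$fit$qr
  if (qrf$rank < ncol(qrf$qr)) fail("rank-deficient design matrix")
  V <- vcov_design(r$fit, r$design)
  structure(list(coefficients = coef_table(r$fit, V, FALSE, level),
                 fit = r$fit, vcov = V, n = stats::nobs(r$fit),
                 separation = FALSE, scale = "beta"),
            class = "svy_lm_fit")
}

#' @export
print.svy_glm_fit <- function(x, ...) {
  cat(sprintf("Survey-weighted %s model, n = %d\n",
              if (x$scale == "odds_ratio") "logistic" else "linear", x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
print.svy_lm_fit <- print.svy_glm_fit

#' Tertile (and categorical) exposure contrasts
#'
#' Extracts the contrasts of upper exposure levels against the reference
#' (first) level from a fitted survey-weighted model, on the odds-ratio
#' scale for logistic fits and the beta scale for linear fits.  The
#' reference row is included with a null contrast (OR 1 / beta 0).
#'
#' @param model a `svy_glm_fit` or `svy_lm_fit` whose formula entered the
#'   exposure as a factor.
#' @param exposure the exposure variable name as it appears in the formula.
#' @return data.frame, one row per exposure level.
#' @export
tertile_contrasts <- function(model, exposure) {
  ct <- model$coefficients
  xlev <- model$fit$xlevels[[exposure]]
  if (is.null(xlev))
    fail("exposure `%s` was not entered as a factor (no reference level found)",
         exposure)
  rows <- ct[ct$term %in% paste0(exposure, xlev[-1L]), , drop = FALSE]
  if (model$scale == "odds_ratio") {
    ref <- data.frame(term = paste0(exposure, xlev[1L]), estimate = 0, se = 0,
                      conf_low = 0, conf_high = 0, p_value = NA_real_,
                      or = 1, or_low = 1, or_high = 1)
  } else {
    ref <- data.frame(term = paste0(exposure, xlev[1L]), estimate = 0, se = 0,
                      conf_low = 0, conf_high = 0, p_value = NA_real_)
  }
  out <- rbind(ref, rows)
  out$level <- xlev
  rownames(out) <- NULL
  out
}
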
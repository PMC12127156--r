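#' Counterfactual mediation analysis of an adiposity indicator
#'
#' Quasi-Bayesian two-model estimator of the average causal mediated effect
#' (ACME), average direct effect (ADE), total effect, and proportion
#' mediated, for a diet-score exposure acting on infertility (binary) or a
#' hormone level (continuous) through BMI or waist circumference.
#'
#' Two survey-weighted component models are fitted: a linear mediator model
#' `mediator ~ exposure + covariates` and an outcome model
#' `outcome ~ exposure + mediator + covariates` (logistic for a binary
#' outcome, linear otherwise), both with robust design-based covariance.
#' `n_draws` parameter vectors are drawn from each model's asymptotic normal
#' sampling distribution; for each draw, potential mediator values under the
#' control and treated exposure levels (sharing the same residual draw) are
#' propagated through the outcome model, and the four weighted
#' potential-outcome means give ACME, ADE, and the total effect on the
#' risk-difference scale (binary outcome) or mean-difference scale
#' (continuous), averaged over the two exposure arms — so total = ACME + ADE
#' holds exactly, draw by draw.  CIs are percentile intervals across draws;
#' everything is deterministic given `seed`.
#'
#' If the total-effect CI covers zero the proportion mediated is flagged
#' unstable and its CI reported as NA rather than a meaningless ratio.
#'
#' @param outcome name of the outcome column (0/1 or continuous).
#' @param exposure name of the exposure column. For a standardized diet
#'   score, `control = 0`, `treat = 1` contrasts a one-SD increase.
#' @param mediator name of the continuous mediator column (BMI kg/m2 or WC cm).
#' @param covariates character vector of adjustment columns.
#' @param data data.frame.
#' @param design a [survey_design()].
#' @param n_draws number of quasi-Bayesian draws (>= 100, default 1000).
#' @param seed integer seed (mandatory for reproducibility).
#' @param control,treat exposure values contrasted.
#' @param level CI level.
#' @return object of class `mediation_result` with elements `acme`, `ade`,
#'   `total_effect`, `prop_mediated` (each a list: estimate, conf_low,
#'   conf_high, p_value), `scale`, `stable_total`, `n`, `n_draws`, `seed`,
#'   and the component fits.
#' @export
mediate_effects <- function(outcome, exposure, mediator,
                            covariates = character(), data, design,
                            n_draws = 1000, seed, control = 0, treat = 1,
                            level = 0.95) {
  if (missing(seed)) fail("`seed` is required for reproducible mediation draws")
  if (n_draws < 100) fail("n_draws must be >= 100")
  used <- c(outcome, exposure, mediator, covariates)
  miss <- setdiff(used, names(data))
  if (length(miss)) fail("column(s) not in data: %s", paste(miss, collapse = ", "))
  keep <- complete.cases(data[, used, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  design <- design_subset(design, keep)
  n <- nrow(data)
  w <- design$weights / sum(design$weights)

  yv <- data[[outcome]]
  binary_y <- all(yv %in% c(0, 1))
  cov_terms <- if (length(covariates)) paste(covariates, collapse = " + ") else NULL

  m_fml <- as.formula(paste(mediator, "~",
                            paste(c(exposure, cov_terms), collapse = " + ")))
  m_mod <- fit_weighted_lm(m_fml, data, design)
  y_fml <- as.formula(paste(outcome, "~",
                            paste(c(exposure, mediator, cov_terms), collapse = " + ")))
  y_mod <- if (binary_y) fit_weighted_glm(y_fml, data, design)
           else fit_weighted_lm(y_fml, data, design)

  # weighted residual SD of the mediator model (df-corrected)
  r <- residuals(m_mod$fit)
  p_m <- length(coef(m_mod$fit))
  sigma_m <- sqrt(sum(design$weights * r^2) / sum(design$weights) * n / (n - p_m))

  set.seed(seed)
  mb <- MASS::mvrnorm(n_draws, coef(m_mod$fit), m_mod$vcov)
  yb <- MASS::mvrnorm(n_draws, coef(y_mod$fit), y_mod$vcov)

  Xm <- model.matrix(m_mod$fit)
  Xy <- model.matrix(y_mod$fit)
  xi_m <- match(exposure, colnames(Xm))
  xi_y <- match(exposure, colnames(Xy))
  mi_y <- match(mediator, colnames(Xy))
  if (any(is.na(c(xi_m, xi_y, mi_y))))
    fail("exposure/mediator must enter the models as single numeric terms")

  linkinv <- if (binary_y) plogis else identity
  acme <- ade <- tau <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    bm <- mb[d, ]; by <- yb[d, ]
    # potential mediator means under the two exposure arms
    Xm0 <- Xm; Xm0[, xi_m] <- control
    mu0 <- drop(Xm0 %*% bm)
    mu1 <- mu0 + bm[xi_m] * (treat - control)
    e <- rnorm(n, 0, sigma_m)            # shared residual draw across arms
    M0 <- mu0 + e; M1 <- mu1 + e
    # outcome linear predictor pieces
    Xy0 <- Xy; Xy0[, xi_y] <- control
    base <- drop(Xy0 %*% by) - by[mi_y] * Xy[, mi_y]
    dx <- by[xi_y] * (treat - control)
    p00 <- sum(w * linkinv(base + by[mi_y] * M0))
    p01 <- sum(w * linkinv(base + by[mi_y] * M1))
    p10 <- sum(w * linkinv(base + dx + by[mi_y] * M0))
    p11 <- sum(w * linkinv(base + dx + by[mi_y] * M1))
    acme[d] <- ((p11 - p10) + (p01 - p00)) / 2
    ade[d]  <- ((p11 - p01) + (p10 - p00)) / 2
    tau[d]  <- p11 - p00
  }

  alpha <- 1 - level
  summ <- function(v) {
    list(estimate = mean(v),
         conf_low = unname(quantile(v, alpha / 2)),
         conf_high = unname(quantile(v, 1 - alpha / 2)),
         p_value = min(1, 2 * min(mean(v > 0), mean(v < 0))))
  }
  a <- summ(acme); de <- summ(ade); te <- summ(tau)
  stable <- !(te$conf_low <= 0 && te$conf_high >= 0)
  prop_draws <- acme / tau
  prop <- list(
    estimate = mean(acme) / mean(tau),
    conf_low = if (stable) unname(quantile(prop_draws, alpha / 2)) else NA_real_,
    conf_high = if (stable) unname(quantile(prop_draws, 1 - alpha / 2)) else NA_real_,
    p_value = a$p_value
  )
  structure(list(acme = a, ade = de, total_effect = te, prop_mediated = prop,
                 scale = if (binary_y) "risk_difference" else "mean_difference",
                 stable_total = stable, n = n, n_draws = n_draws, seed = seed,
                 exposure = exposure, mediator = mediator, outcome = outcome,
                 control = control, treat = treat,
                 mediator_model = m_mod, outcome_model = y_mod),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation of %s -> %s via %s (%s scale), n = %d, %d draws\n",
              x$exposure, x$outcome, x$mediator, x$scale, x$n, x$n_draws))
  for (nm in c("acme", "ade", "total_effect")) {
    e <- x[[nm]]
    cat(sprintf("  %-13s %9.5f [%9.5f, %9.5f]  p = %.3g\n", nm,
                e$estimate, e$conf_low, e$conf_high, e$p_value))
  }
  p <- x$prop_mediated
  cat(sprintf("  %% mediated    %8.2f%%", 100 * p$estimate))
  if (x$stable_total)
    cat(sprintf("  [%.2f%%, %.2f%%]\n", 100 * p$conf_low, 100 * p$conf_high))
  else cat("  (total effect indistinguishable from 0; proportion unstable)\n")
  invisible(x)
}

#' Tidy summary of mediation results
#'
#' One row per (exposure, mediator, outcome) triple with ACME, ADE, total
#' effect, CIs, p-value stars, and the percent mediated (100 * ACME / total).
#'
#' @param results a single `mediation_result` or a list of them.
#' @return data.frame.
#' @export
mediation_table <- function(results) {
  if (inherits(results, "mediation_result")) results <- list(results)
  if (length(results) < 1L) fail("need at least one mediation result")
  stars <- function(p) ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  rows <- lapply(results, function(x) {
    data.frame(
      exposure = x$exposure, mediator = x$mediator, outcome = x$outcome,
      scale = x$scale,
      acme = x$acme$estimate, acme_low = x$acme$conf_low,
      acme_high = x$acme$conf_high, acme_p = x$acme$p_value,
      acme_sig = stars(x$acme$p_value),
      ade = x$ade$estimate, ade_low = x$ade$conf_low,
      ade_high = x$ade$conf_high, ade_p = x$ade$p_value,
      total = x$total_effect$estimate, total_low = x$total_effect$conf_low,
      total_high = x$total_effect$conf_high, total_p = x$total_effect$p_value,
      pct_mediated = 100 * x$prop_mediated$estimate,
      pct_mediated_low = 100 * x$prop_mediated$conf_low,
      pct_mediated_high = 100 * x$prop_mediated$conf_high,
      stable_total = x$stable_total, n = x$n, n_draws = x$n_draws,
      seed = x$seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
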
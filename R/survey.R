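#' Survey design descriptor
#'
#' Bundles the dietary-day sampling weights (the WTDRD1 role in NHANES-style
#' analyses) with optional stratum and primary-sampling-unit identifiers.
#' Two variance modes are supported: `"weights_only_robust"` treats
#' observations as independently sampled with unequal probabilities and uses
#' the with-replacement sandwich/linearization estimator; `"taylor"` performs
#' stratified between-PSU Taylor linearization and requires both `strata` and
#' `psu`.
#'
#' @param weights positive sampling weights, one per observation.
#' @param strata optional stratum identifiers.
#' @param psu optional primary-sampling-unit identifiers.
#' @param variance_mode `"weights_only_robust"` (default) or `"taylor"`.
#' @return an object of class `svy_design`.
#' @export
survey_design <- function(weights, strata = NULL, psu = NULL,
                          variance_mode = c("weights_only_robust", "taylor")) {
  variance_mode <- match.arg(variance_mode)
  if (!is.numeric(weights) || length(weights) < 1L)
    fail("`weights` must be a non-empty numeric vector")
  if (any(!is.finite(weights)) || any(weights <= 0))
    fail("all survey weights must be finite and positive")
  if (variance_mode == "taylor" && (is.null(strata) || is.null(psu)))
    fail("taylor variance mode requires both `strata` and `psu`")
  if (!is.null(strata) && length(strata) != length(weights))
    fail("`strata` must match `weights` in length")
  if (!is.null(psu) && length(psu) != length(weights))
    fail("`psu` must match `weights` in length")
  structure(
    list(weights = as.numeric(weights), strata = strata, psu = psu,
         variance_mode = variance_mode),
    class = "svy_design"
  )
}

#' Subset a survey design
#'
#' @param design a [survey_design()].
#' @param idx logical or integer row index.
#' @return the restricted `svy_design`.
#' @export
design_subset <- function(design, idx) {
  survey_design(design$weights[idx],
                strata = if (!is.null(design$strata)) design$strata[idx],
                psu = if (!is.null(design$psu)) design$psu[idx],
                variance_mode = design$variance_mode)
}

# Linearization variance of the Hajek ratio mean under the design.
# weights_only mode: var = n/(n-1) * sum(u_i^2), u_i = w_i (x_i - mean)/sum(w);
# taylor mode aggregates u within PSUs and takes stratified between-PSU sums.
mean_lin_var <- function(x, design) {
  w <- design$weights
  m <- sum(w * x) / sum(w)
  u <- w * (x - m) / sum(w)
  if (design$variance_mode == "taylor") {
    v <- 0
    for (h in unique(design$strata)) {
      ih <- which(design$strata == h)
      uh <- tapply(u[ih], design$psu[ih], sum)
      nh <- length(uh)
      if (nh < 2L) next  # single-PSU stratum contributes no variance (certainty)
      v <- v + nh / (nh - 1) * sum((uh - mean(uh))^2)
    }
    list(mean = m, var = v)
  } else {
    n <- length(x)
    list(mean = m, var = n / (n - 1) * sum(u^2))
  }
}

#' Survey-weighted mean and standard error
#'
#' Hajek (ratio) estimator of the population mean with a linearization
#' standard error.  With equal weights in `weights_only_robust` mode this
#' reduces exactly to the sample mean and `sd(x)/sqrt(n)`.
#'
#' @param values numeric vector (at least 2 observations).
#' @param design a [survey_design()].
#' @return named numeric vector `c(mean, se)`.
#' @export
weighted_mean_se <- function(values, design) {
  stopifnot(inherits(design, "svy_design"))
  keep <- is.finite(values)
  if (sum(keep) < 2L) fail("need at least 2 finite observations")
  if (!all(keep)) design <- design_subset(design, keep)
  r <- mean_lin_var(values[keep], design)
  c(mean = r$mean, se = sqrt(r$var))
}

#' Survey-weighted category percentages
#'
#' @param categories factor or character vector.
#' @param design a [survey_design()].
#' @return data.frame with `level`, `n` (unweighted count), and `percent`
#'   (weighted, summing to 100).
#' @export
weighted_percent <- function(categories, design) {
  stopifnot(inherits(design, "svy_design"))
  keep <- !is.na(categories)
  if (!any(keep)) fail("no non-missing categories")
  categories <- factor(categories[keep])
  w <- design$weights[keep]
  tw <- tapply(w, categories, sum, default = 0)
  data.frame(
    level = names(tw),
    n = as.integer(table(categories)),
    percent = as.numeric(100 * tw / sum(w)),
    row.names = NULL
  )
}

# Kish design effect: 1 exactly under equal weights.
kish_deff <- function(w) length(w) * sum(w^2) / sum(w)^2

#' Design-weighted group comparison test
#'
#' Continuous variables: two groups are compared with a weighted Welch-type
#' t-test (group means and variances from the design linearization,
#' Satterthwaite degrees of freedom); more than two groups with a Wald F test
#' of equality of the weighted group means.  Categorical variables: Pearson
#' chi-square computed on the weighted contingency table rescaled to the
#' observed sample size, with a first-order Kish design-effect correction.
#' Under equal weights both reduce exactly to their classical counterparts
#' (`t.test()` / `chisq.test(correct = FALSE)`).
#'
#' @param values numeric vector (continuous) or factor/character (categorical).
#' @param groups grouping factor with >= 2 levels.
#' @param design a [survey_design()].
#' @return list with `p_value`, `statistic`, `df`, and `type`.
#' @export
group_test <- function(values, groups, design) {
  stopifnot(inherits(design, "svy_design"))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  design <- design_subset(design, keep)
  if (nlevels(groups) < 2L) fail("need at least 2 groups")
  if (any(table(groups) < 2L)) fail("every group needs at least 2 observations")
  if (is.numeric(values)) group_test_continuous(values, groups, design)
  else group_test_categorical(values, groups, design)
}

group_test_continuous <- function(values, groups, design) {
  lev <- levels(groups)
  est <- vapply(lev, function(g) {
    i <- groups == g
    r <- mean_lin_var(values[i], design_subset(design, i))
    c(r$mean, r$var)
  }, numeric(2))
  m <- est[1, ]; v <- est[2, ]
  ng <- as.integer(table(groups))
  m <- unname(m); v <- unname(v)
  if (length(lev) == 2L) {
    stat <- (m[1] - m[2]) / sqrt(v[1] + v[2])
    df <- (v[1] + v[2])^2 / (v[1]^2 / (ng[1] - 1) + v[2]^2 / (ng[2] - 1))
    list(p_value = 2 * pt(-abs(stat), df), statistic = stat, df = df,
         type = "weighted_welch_t")
  } else {
    # Wald F across G-1 differences from the first group's mean
    d <- m[-1] - m[1]
    Vd <- diag(v[-1], nrow = length(d)) + v[1]
    stat <- drop(t(d) %*% solve(Vd, d)) / length(d)
    df2 <- length(values) - length(lev)
    list(p_value = pf(stat, length(d), df2, lower.tail = FALSE),
         statistic = stat, df = c(length(d), df2), type = "weighted_wald_f")
  }
}

group_test_categorical <- function(values, groups, design) {
  values <- factor(values)
  if (nlevels(values) < 2L) fail("categorical variable needs >= 2 levels")
  w <- design$weights
  n <- length(w)
  # weighted cell proportions rescaled to the observed n
  tab <- tapply(w, list(groups, values), sum, default = 0)
  tab <- tab / sum(w) * n
  expd <- outer(rowSums(tab), colSums(tab)) / n
  x2 <- sum((tab - expd)^2 / expd)
  x2 <- x2 / kish_deff(w)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(p_value = pchisq(x2, df, lower.tail = FALSE), statistic = x2, df = df,
       type = "deff_corrected_chisq")
}

#' Descriptive ("Table 1") summary by group
#'
#' Builds the standard epidemiological baseline table: weighted mean (SE) for
#' continuous variables, n (weighted %) for categorical variables, with a
#' design-weighted group test per variable.
#'
#' @param data data.frame holding the variables.
#' @param vars character vector of column names to summarise.
#' @param group column name of the grouping variable (or NULL for overall
#'   summaries without tests).
#' @param design a [survey_design()] aligned with `data` rows.
#' @return data.frame with columns `variable`, `level`, one summary column per
#'   group, and `p_value`.
#' @export
table_one <- function(data, vars, group = NULL, design) {
  stopifnot(inherits(design, "svy_design"))
  glev <- if (is.null(group)) "overall" else levels(factor(data[[group]]))
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) fail("variable `%s` not found", v)
    if (is.numeric(x)) {
      cells <- vapply(glev, function(g) {
        i <- if (is.null(group)) rep(TRUE, nrow(data)) else
          !is.na(data[[group]]) & data[[group]] == g
        i <- i & is.finite(x)
        ms <- weighted_mean_se(x[i], design_subset(design, i))
        sprintf("%.2f (%.2f)", ms["mean"], ms["se"])
      }, character(1))
      p <- if (is.null(group)) NA_real_ else
        group_test(x, data[[group]], design)$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "", t(cells), p_value = p,
        check.names = FALSE)
    } else {
      xf <- factor(x)
      p <- if (is.null(group)) NA_real_ else
        group_test(xf, data[[group]], design)$p_value
      for (lv in levels(xf)) {
        cells <- vapply(glev, function(g) {
          i <- if (is.null(group)) rep(TRUE, nrow(data)) else
            !is.na(data[[group]]) & data[[group]] == g
          i <- i & !is.na(xf)
          wp <- weighted_percent(xf[i], design_subset(design, i))
          row <- wp[wp$level == lv, ]
          if (nrow(row) == 0L) "0 (0.00)" else
            sprintf("%d (%.2f)", row$n, row$percent)
        }, character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, t(cells),
          p_value = if (lv == levels(xf)[1L]) p else NA_real_,
          check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + length(glev))] <- glev
  rownames(out) <- NULL
  out
}
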
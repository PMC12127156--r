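#' Apply cohort eligibility filters
#'
#' Sequentially excludes (a) males, (b) women aged below 20 or above 45,
#' (c) records missing any active DII/DOBS dietary component, and
#' (d) records missing any outcome or mediating variable, logging the number
#' removed at each step (the selection-flowchart analogue).
#'
#' @param data participant-level data.frame; needs `sex` ("female"/"male" or
#'   1/2 NHANES coding where 2 = female), `age`, the dietary component
#'   columns, and the outcome/mediator columns.
#' @param components character vector of dietary component columns that must
#'   be non-missing (default: union of the bundled DII and DOBS components).
#' @param outcome_vars columns counted as outcomes/mediators for step (d).
#' @param age_range inclusive eligible age interval in years.
#' @return list of class `analytic_cohort`: `records` (the retained
#'   data.frame) and `exclusion_log` (data.frame of step, n_removed,
#'   n_remaining).
#' @export
apply_exclusions <- function(data,
                             components = union(dii_reference()$component,
                                                dobs_reference()$component),
                             outcome_vars = c("infertility", "shbg", "tt",
                                              "e2", "bmi", "wc"),
                             age_range = c(20, 45)) {
  steps <- list()
  n0 <- nrow(data)
  is_female <- if (is.numeric(data$sex)) data$sex == 2 else data$sex == "female"
  is_female[is.na(is_female)] <- FALSE
  data <- data[is_female, , drop = FALSE]
  steps$male <- n0 - nrow(data)

  n1 <- nrow(data)
  ok_age <- !is.na(data$age) & data$age >= age_range[1] & data$age <= age_range[2]
  data <- data[ok_age, , drop = FALSE]
  steps$age_out_of_range <- n1 - nrow(data)

  n2 <- nrow(data)
  comp_present <- intersect(components, names(data))
  if (length(comp_present) < length(components))
    fail("dietary component column(s) absent from data: %s",
         paste(setdiff(components, comp_present), collapse = ", "))
  ok_diet <- complete.cases(data[, comp_present, drop = FALSE])
  data <- data[ok_diet, , drop = FALSE]
  steps$missing_diet_component <- n2 - nrow(data)

  n3 <- nrow(data)
  out_present <- intersect(outcome_vars, names(data))
  ok_out <- complete.cases(data[, out_present, drop = FALSE])
  data <- data[ok_out, , drop = FALSE]
  steps$missing_outcome_or_mediator <- n3 - nrow(data)

  log <- data.frame(step = names(steps),
                    n_removed = as.integer(unlist(steps)))
  log$n_remaining <- n0 - cumsum(log$n_removed)
  if (nrow(data) == 0L) warning("no records remain after exclusions")
  structure(list(records = data, exclusion_log = log),
            class = "analytic_cohort")
}

#' Homeostatic model assessment of insulin resistance
#'
#' HOMA-IR = fasting insulin (mU/L) x fasting glucose (mmol/L) / 22.5.
#'
#' @param insulin fasting insulin, mU/L (>= 0).
#' @param glucose fasting glucose, mmol/L (>= 0).
#' @return numeric HOMA-IR.
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE))
    fail("insulin and glucose must be non-negative")
  insulin * glucose / 22.5
}

#' Obesity and central-adiposity classification
#'
#' Boundary-inclusive thresholds: BMI >= 30.0 kg/m2 is "obese"; waist
#' circumference >= 88 cm (women) is "high_wc".
#'
#' @param bmi body mass index, kg/m2 (> 0).
#' @return factor with levels `nonobese`, `obese`.
#' @export
classify_obesity <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) fail("bmi must be positive")
  factor(ifelse(bmi >= 30.0, "obese", "nonobese"),
         levels = c("nonobese", "obese"))
}

#' @rdname classify_obesity
#' @param wc waist circumference, cm (> 0).
#' @export
classify_wc <- function(wc) {
  if (any(wc <= 0, na.rm = TRUE)) fail("wc must be positive")
  factor(ifelse(wc >= 88, "high_wc", "normal"),
         levels = c("normal", "high_wc"))
}

#' Dichotomize a biomarker at its (weighted) median
#'
#' The cutpoint is the survey-weighted median (see [weighted_median()]);
#' values strictly above the cutpoint are coded 1 ("high"), values at or
#' below it 0.  Weights default to equal, and rescaling all weights leaves
#' the labels unchanged.
#'
#' @param values numeric vector with >= 2 finite values, not all identical.
#' @param weights positive survey weights (default equal).
#' @return integer 0/1 vector with the cutpoint attached as attribute
#'   `"cutpoint"`.
#' @export
dichotomize_at_median <- function(values, weights = NULL) {
  fin <- values[is.finite(values)]
  if (length(fin) < 2L) fail("need at least 2 finite values")
  if (length(unique(fin)) == 1L) fail("all values identical; median split undefined")
  cut <- weighted_median(values, weights)
  structure(as.integer(values > cut), cutpoint = cut)
}

#' Code covariates into model-ready categories
#'
#' Produces the adjustment set used throughout the regression models: age
#' (years, continuous), race (4 named levels + other), education (4 levels),
#' marital status (2 levels), PIR coded `<1` / `>=1` / `miss` (missing income
#' kept as its own category, not dropped), smoking (never/former/current),
#' physical activity dichotomized at 600 MET-min/week (boundary inclusive in
#' the active group), and total energy intake (kcal, continuous).
#'
#' @param data data.frame with columns `age`, `race`, `education`, `marital`,
#'   `pir` (numeric, NA allowed), `smoking`, `physical_activity` (MET-min/
#'   week), `total_energy`.
#' @return data.frame of coded covariates aligned with `data`.
#' @export
code_covariates <- function(data) {
  race_lev <- c("nonhispanic_white", "nonhispanic_black", "mexican_american",
                "other")
  edu_lev <- c("below_high_school", "high_school", "some_college",
               "college_graduate")
  mar_lev <- c("married_or_partner", "live_alone")
  smk_lev <- c("never", "former", "current")
  chk <- function(x, lev, name) {
    bad <- setdiff(unique(as.character(x[!is.na(x)])), lev)
    if (length(bad)) fail("unknown %s category: %s", name, paste(bad, collapse = ", "))
    factor(x, levels = lev)
  }
  pir_cat <- ifelse(is.na(data$pir), "miss", ifelse(data$pir < 1, "lt1", "ge1"))
  pa_cat <- ifelse(data$physical_activity >= 600, "ge600", "lt600")
  data.frame(
    age = as.numeric(data$age),
    race = chk(data$race, race_lev, "race"),
    education = chk(data$education, edu_lev, "education"),
    marital = chk(data$marital, mar_lev, "marital"),
    pir_cat = factor(pir_cat, levels = c("lt1", "ge1", "miss")),
    smoking = chk(data$smoking, smk_lev, "smoking"),
    pa_cat = factor(pa_cat, levels = c("ge600", "lt600")),
    total_energy = as.numeric(data$total_energy)
  )
}

#' Read a participant table from CSV or SAS transport format
#'
#' Thin reader for the two source formats the survey distributes; an optional
#' variable map renames source codebook columns (e.g. `RHQ074`, `BMXBMI`,
#' `WTDRD1`) to the internal field names used throughout this package.
#'
#' @param path a `.csv` or `.xpt` file.
#' @param var_map optional named character vector or YAML file path mapping
#'   source column names to internal names (`c(BMXBMI = "bmi")`).
#' @return data.frame.
#' @export
read_cohort <- function(path, var_map = NULL) {
  if (!file.exists(path)) fail("input file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  data <- switch(ext,
    csv = read.csv(path, stringsAsFactors = FALSE),
    xpt = {
      if (!requireNamespace("foreign", quietly = TRUE))
        fail("reading .xpt requires the `foreign` package")
      foreign::read.xport(path)
    },
    fail("unsupported input format: .%s", ext))
  if (!is.null(var_map)) {
    if (is.character(var_map) && length(var_map) == 1L && file.exists(var_map))
      var_map <- unlist(yaml::read_yaml(var_map))
    hit <- names(var_map) %in% names(data)
    names(data)[match(names(var_map)[hit], names(data))] <- var_map[hit]
  }
  data
}
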
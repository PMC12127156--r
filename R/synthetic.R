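#' Configuration for the synthetic NHANES-like cohort generator
#'
#' Defines the generating model for a cohort of women of reproductive age
#' with a latent standardized diet score driving dietary intakes, adiposity
#' mediators, and reproductive outcomes through planted paths:
#' * `path_a` — effect of the standardized score on the mediator (BMI,
#'   kg/m2 per score SD); waist circumference tracks BMI.
#' * `path_b` — effect of BMI on the infertility logit (per kg/m2).
#' * `path_c` — direct effect of the score on the infertility logit (per SD).
#'
#' Dietary intakes are log-normal (positive and right-skewed, as nutrient
#' intakes are), centred so the median intake of each component matches its
#' global reference mean, with a signed loading on the latent score so that
#' pro-inflammatory components rise and anti-inflammatory components fall
#' with it.  Alcohol is zero-inflated to produce nondrinkers.  Survey
#' weights are drawn from a shifted gamma with mean 1.  Covariate effects on
#' the outcome default to zero, so with all paths zero the infertility
#' prevalence is exactly `plogis(outcome_intercept + path_b * 0 ...)` in
#' expectation.
#'
#' Defaults emulate the study conditions: n = 1774 women aged 20-45 and a
#' baseline infertility prevalence of 12.66%.
#'
#' @param n_participants cohort size (>= 1).
#' @param seed integer seed.
#' @param path_a,path_b,path_c planted mediation paths (see above).
#' @param outcome_intercept infertility-model intercept on the logit scale;
#'   default places baseline prevalence at 12.66% given `path_b` and the
#'   mean BMI.
#' @param intake_spec data.frame `component`, `meanlog`, `sdlog`, `loading`
#'   (default derived from the bundled DII/DOBS component lists).
#' @param weight_spec list `shape`, `min` for the shifted-gamma weights.
#' @param mediator_spec list `bmi_base`, `bmi_sd`, `wc_base`, `wc_slope`,
#'   `wc_sd`.
#' @param shbg_model list `intercept`, `beta_score`, `beta_mediator` (per
#'   kg/m2 BMI above base), `sd` — linear Gaussian SHBG (nmol/L).
#' @param covariate_spec list of category probabilities and distribution
#'   parameters for age, race, education, marital status, PIR, smoking,
#'   physical activity, lipids, insulin, glucose.
#' @param outcome_covariate_effects named list of additional outcome-logit
#'   coefficients on covariate columns (default none).
#' @param design_blocks emit balanced stratum/PSU identifiers.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1774, seed = 20130101,
                          path_a = 0.8, path_b = 0.08, path_c = 0.15,
                          outcome_intercept = NULL,
                          intake_spec = default_intake_spec(),
                          weight_spec = list(shape = 4, min = 0.25),
                          mediator_spec = list(bmi_base = 28, bmi_sd = 4.5,
                                               wc_base = 92, wc_slope = 2.2,
                                               wc_sd = 6),
                          shbg_model = list(intercept = 62, beta_score = -6,
                                            beta_mediator = -1.5, sd = 22),
                          covariate_spec = default_covariate_spec(),
                          outcome_covariate_effects = list(),
                          design_blocks = FALSE) {
  check_number(n_participants, "n_participants", lower = 1)
  check_number(seed, "seed")
  check_number(path_a, "path_a"); check_number(path_b, "path_b")
  check_number(path_c, "path_c")
  if (is.null(outcome_intercept))
    outcome_intercept <- qlogis(0.1266) - path_b * mediator_spec$bmi_base
  check_number(outcome_intercept, "outcome_intercept")
  need <- c("component", "meanlog", "sdlog", "loading")
  if (!all(need %in% names(intake_spec)))
    fail("intake_spec must have columns %s", paste(need, collapse = ", "))
  if (any(intake_spec$sdlog <= 0)) fail("intake_spec$sdlog must be > 0")
  for (f in c("bmi_sd", "wc_sd"))
    check_number(mediator_spec[[f]], paste0("mediator_spec$", f), 0, strict = TRUE)
  check_number(shbg_model$sd, "shbg_model$sd", 0, strict = TRUE)
  check_number(weight_spec$shape, "weight_spec$shape", 0, strict = TRUE)
  for (p in c("race_probs", "education_probs", "marital_probs", "smoking_probs")) {
    pr <- covariate_spec[[p]]
    if (abs(sum(pr) - 1) > 1e-9) fail("covariate_spec$%s must sum to 1", p)
    if (any(pr < 0)) fail("covariate_spec$%s must be non-negative", p)
  }
  structure(list(n_participants = as.integer(n_participants), seed = seed,
                 path_a = path_a, path_b = path_b, path_c = path_c,
                 outcome_intercept = outcome_intercept,
                 intake_spec = intake_spec, weight_spec = weight_spec,
                 mediator_spec = mediator_spec, shbg_model = shbg_model,
                 covariate_spec = covariate_spec,
                 outcome_covariate_effects = outcome_covariate_effects,
                 design_blocks = design_blocks),
            class = "cohort_config")
}

#' Default intake generating spec for all DII/DOBS components
#'
#' Log-normal location set so the median intake equals the component's global
#' reference mean; dispersion 0.5 on the log scale; loading +/- 0.25 SD per
#' latent-score SD, signed by the component's inflammatory direction (DOBS-
#' only anti-oxidants calcium and copper load negatively, like the other
#' anti-oxidants).
#'
#' @return data.frame `component`, `meanlog`, `sdlog`, `loading`.
#' @export
default_intake_spec <- function() {
  dii <- dii_reference()
  spec <- data.frame(component = dii$component,
                     meanlog = log(dii$global_mean),
                     sdlog = 0.5,
                     loading = 0.25 * sign(dii$effect_score))
  extra <- data.frame(component = c("calcium", "copper"),
                      meanlog = log(c(900, 1.2)), sdlog = 0.5,
                      loading = c(-0.25, -0.25))
  rbind(spec, extra)
}

#' @rdname default_intake_spec
#' @export
default_covariate_spec <- function() {
  list(
    age_range = c(20, 45),
    race_levels = c("nonhispanic_white", "nonhispanic_black",
                    "mexican_american", "other"),
    race_probs = c(0.56, 0.14, 0.11, 0.19),
    education_levels = c("below_high_school", "high_school", "some_college",
                         "college_graduate"),
    education_probs = c(0.12, 0.20, 0.36, 0.32),
    marital_levels = c("married_or_partner", "live_alone"),
    marital_probs = c(0.62, 0.38),
    pir_shape = 2.2, pir_rate = 0.9, pir_missing = 0.08,
    smoking_levels = c("never", "former", "current"),
    smoking_probs = c(0.66, 0.16, 0.18),
    pa_meanlog = log(600), pa_sdlog = 1.1,
    tc_mean = 4.7, tc_sd = 0.9, tg_meanlog = log(1.1), tg_sdlog = 0.5,
    hdl_mean = 1.4, hdl_sd = 0.35, ldl_mean = 2.7, ldl_sd = 0.8,
    insulin_meanlog = log(10), insulin_sdlog = 0.55,
    glucose_mean = 5.3, glucose_sd = 0.6,
    alcohol_p_drink = 0.5
  )
}

#' Generate a synthetic cohort with planted mediation structure
#'
#' Deterministic given the config seed; each variable is drawn from its own
#' deterministic sub-stream, so adding a variable to the generator does not
#' perturb the draws of existing ones.  See [cohort_config()] for the
#' generating model.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `data` (one row per
#'   participant: id, sex, survey weight, latent `diet_score`, intakes,
#'   covariates, mediators, outcomes) and `truth` (the generating
#'   coefficients).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  n <- config$n_participants
  cs <- config$covariate_spec
  seed <- config$seed

  d <- with_substream(seed, "diet_score", rnorm(n))

  intakes <- list()
  for (j in seq_len(nrow(config$intake_spec))) {
    comp <- config$intake_spec$component[j]
    ml <- config$intake_spec$meanlog[j]
    sl <- config$intake_spec$sdlog[j]
    ld <- config$intake_spec$loading[j]
    intakes[[comp]] <- with_substream(seed, paste0("intake_", comp), {
      amt <- exp(ml + ld * d + sl * rnorm(n))
      if (comp == "alcohol") {
        drink <- rbinom(n, 1, cs$alcohol_p_drink)
        amt * drink
      } else amt
    })
  }

  ws <- config$weight_spec
  survey_weight <- with_substream(seed, "survey_weight",
    ws$min + rgamma(n, shape = ws$shape, rate = ws$shape / (1 - ws$min)))

  age <- with_substream(seed, "age", runif(n, cs$age_range[1], cs$age_range[2]))
  draw_cat <- function(name, levels, probs)
    with_substream(seed, name,
                   levels[sample.int(length(levels), n, TRUE, probs)])
  race <- draw_cat("race", cs$race_levels, cs$race_probs)
  education <- draw_cat("education", cs$education_levels, cs$education_probs)
  marital <- draw_cat("marital", cs$marital_levels, cs$marital_probs)
  smoking <- draw_cat("smoking", cs$smoking_levels, cs$smoking_probs)
  pir <- with_substream(seed, "pir", {
    v <- rgamma(n, cs$pir_shape, cs$pir_rate)
    v[runif(n) < cs$pir_missing] <- NA
    v
  })
  physical_activity <- with_substream(seed, "physical_activity",
                                      rlnorm(n, cs$pa_meanlog, cs$pa_sdlog))
  tc <- with_substream(seed, "tc", rnorm(n, cs$tc_mean, cs$tc_sd))
  tg <- with_substream(seed, "tg", rlnorm(n, cs$tg_meanlog, cs$tg_sdlog))
  hdl <- with_substream(seed, "hdl", rnorm(n, cs$hdl_mean, cs$hdl_sd))
  ldl <- with_substream(seed, "ldl", rnorm(n, cs$ldl_mean, cs$ldl_sd))
  insulin <- with_substream(seed, "insulin",
                            rlnorm(n, cs$insulin_meanlog, cs$insulin_sdlog))
  glucose <- with_substream(seed, "glucose",
                            abs(rnorm(n, cs$glucose_mean, cs$glucose_sd)))

  ms <- config$mediator_spec
  bmi <- with_substream(seed, "bmi",
                        ms$bmi_base + config$path_a * d + rnorm(n, 0, ms$bmi_sd))
  wc <- with_substream(seed, "wc",
                       ms$wc_base + ms$wc_slope * (bmi - ms$bmi_base) +
                         rnorm(n, 0, ms$wc_sd))

  cov_lp <- rep(0, n)
  covs <- list(age = age, pir = ifelse(is.na(pir), 0, pir),
               physical_activity = physical_activity)
  for (nm in names(config$outcome_covariate_effects))
    cov_lp <- cov_lp + config$outcome_covariate_effects[[nm]] * covs[[nm]]

  eta <- config$outcome_intercept + config$path_c * d + config$path_b * bmi +
    cov_lp
  infertility <- with_substream(seed, "infertility", rbinom(n, 1, plogis(eta)))

  sm <- config$shbg_model
  shbg <- with_substream(seed, "shbg",
    sm$intercept + sm$beta_score * d + sm$beta_mediator * (bmi - ms$bmi_base) +
      rnorm(n, 0, sm$sd))
  tt <- with_substream(seed, "tt", rlnorm(n, log(30), 0.4))
  e2 <- with_substream(seed, "e2", rlnorm(n, log(100), 0.5))

  data <- data.frame(participant_id = seq_len(n), sex = "female",
                     survey_weight = survey_weight, diet_score = d,
                     as.data.frame(intakes, check.names = FALSE),
                     age = age, race = race, education = education,
                     marital = marital, pir = pir, smoking = smoking,
                     physical_activity = physical_activity,
                     total_energy = intakes$energy,
                     tc = tc, tg = tg, hdl = hdl, ldl = ldl,
                     insulin = insulin, glucose = glucose,
                     bmi = bmi, wc = wc, infertility = infertility,
                     shbg = shbg, tt = tt, e2 = e2,
                     check.names = FALSE)
  if (config$design_blocks) {
    n_strata <- max(1L, min(15L, n %/% 120L))
    data$stratum <- rep_len(seq_len(n_strata), n)
    data$psu <- rep_len(1:2, n)
  }
  truth <- list(path_a = config$path_a, path_b = config$path_b,
                path_c = config$path_c,
                outcome_intercept = config$outcome_intercept,
                mediator_spec = ms, shbg_model = sm,
                outcome_covariate_effects = config$outcome_covariate_effects)
  structure(list(data = data, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Generating-model proportion mediated (oracle)
#'
#' Computes the true proportion of the exposure effect on infertility that
#' is mediated by BMI, by Monte-Carlo evaluation of the generating model's
#' counterfactual means on the risk-difference scale: mediator noise (and
#' any covariate terms, over the simulated covariate distribution) is
#' integrated out by simulation, and ACME/(ACME + ADE) is returned for the
#' exposure contrast `control -> treat`.
#'
#' @param cohort a `synthetic_cohort` (its `truth` defines the model).
#' @param control,treat exposure (standardized score) values contrasted.
#' @param n_draws Monte-Carlo draws.
#' @param seed seed for the oracle simulation.
#' @return scalar proportion mediated (in \[0, 1\] when the paths share sign),
#'   with components `acme`, `ade`, `total` as attributes.
#' @export
true_proportion_mediated <- function(cohort, control = 0, treat = 1,
                                     n_draws = 1e5, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  ms <- tr$mediator_spec
  set.seed(seed)
  e <- rnorm(n_draws, 0, ms$bmi_sd)
  cov_lp <- rep(0, n_draws)
  if (length(tr$outcome_covariate_effects)) {
    idx <- sample.int(nrow(cohort$data), n_draws, replace = TRUE)
    covs <- list(age = cohort$data$age,
                 pir = ifelse(is.na(cohort$data$pir), 0, cohort$data$pir),
                 physical_activity = cohort$data$physical_activity)
    for (nm in names(tr$outcome_covariate_effects))
      cov_lp <- cov_lp + tr$outcome_covariate_effects[[nm]] * covs[[nm]][idx]
  }
  m_of <- function(t) ms$bmi_base + tr$path_a * t + e
  p_of <- function(t, m)
    mean(plogis(tr$outcome_intercept + tr$path_c * t + tr$path_b * m + cov_lp))
  p11 <- p_of(treat, m_of(treat));   p10 <- p_of(treat, m_of(control))
  p01 <- p_of(control, m_of(treat)); p00 <- p_of(control, m_of(control))
  acme <- ((p11 - p10) + (p01 - p00)) / 2
  ade <- ((p11 - p01) + (p10 - p00)) / 2
  total <- p11 - p00
  if (abs(total) < 1e-12)
    fail("total effect is numerically zero; proportion mediated undefined")
  structure(acme / total, acme = acme, ade = ade, total = total)
}

#' Write a synthetic cohort to disk
#'
#' Emits the participant table as CSV, the generating configuration as YAML,
#' and the truth coefficients as a JSON sidecar.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = file.path(dir, "cohort.csv"),
             config = file.path(dir, "config.yaml"),
             truth = file.path(dir, "truth.json"))
  write.csv(cohort$data, paths["data"], row.names = FALSE)
  cfg <- cohort$config
  cfg$intake_spec <- as.list(cfg$intake_spec)
  yaml::write_yaml(unclass(cfg), paths["config"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
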
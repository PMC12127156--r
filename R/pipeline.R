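core_covariates <- c("age", "race", "education", "marital", "pir_cat",
                     "smoking", "pa_cat", "total_energy")
extended_covariates <- c(core_covariates, "tc", "tg", "ldl", "hdl", "homa_ir")

#' Assemble the model-ready covariate frame
#'
#' Runs [code_covariates()] and appends the extended-adjustment variables
#' (lipids and HOMA-IR, the latter derived from fasting insulin and glucose).
#'
#' @param data analytic cohort rows.
#' @param set `"core"` or `"extended"`.
#' @return data.frame of covariates (named per the set definition).
#' @export
model_covariates <- function(data, set = c("core", "extended")) {
  set <- match.arg(set)
  out <- code_covariates(data)
  if (set == "extended") {
    out$tc <- data$tc; out$tg <- data$tg
    out$ldl <- data$ldl; out$hdl <- data$hdl
    out$homa_ir <- homa_ir(data$insulin, data$glucose)
  }
  out
}

#' Score a cohort: DII, DOBS, tertiles, and joint diet class
#'
#' @param data participant table containing all DII/DOBS component columns
#'   and `participant_id`.
#' @param dii_params a `dii_params` table (default bundled reference).
#' @param dobs_spec a `dobs_spec` (default bundled reference).
#' @return `data` with columns `dii`, `dobs`, `dii_tertile`, `dobs_tertile`
#'   (factors T1-T3), and `diet_class` appended.
#' @export
score_cohort <- function(data, dii_params = dii_reference(),
                         dobs_spec = dobs_reference()) {
  dii <- compute_dii(data, dii_params)
  dobs <- compute_dobs(data, dobs_spec)
  data$dii <- dii$dii
  data$dobs <- dobs$dobs
  data$dii_tertile <- factor(paste0("T", assign_tertiles(data$dii)),
                             levels = c("T1", "T2", "T3"))
  data$dobs_tertile <- factor(paste0("T", assign_tertiles(data$dobs)),
                              levels = c("T1", "T2", "T3"))
  data$diet_class <- classify_diet(data$dii, data$dobs)
  data
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    fail("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates scoring, eligibility filtering, weighted descriptives,
#' logistic and linear exposure models, restricted-cubic-spline
#' dose-response, and obesity mediation from a single configuration, on
#' simulated or supplied input, writing one CSV per output surface plus a
#' JSON run manifest.  All numbers come from the exported module functions;
#' the orchestrator computes nothing itself.  Given identical config and
#' input the outputs are byte-identical across runs.
#'
#' @param config list with elements:
#'   * `input`: data.frame, path (CSV/XPT), or NULL to simulate;
#'   * `cohort_config`: arguments for [cohort_config()] when simulating;
#'   * `dii_params`, `dobs_spec`: optional paths/tables (default bundled);
#'   * `out_dir`: output directory;
#'   * `seed`: global seed for stochastic stages (mediation draws);
#'   * `rcs_k`: knot count (default 4);
#'   * `mediation`: logical (default TRUE); `n_draws` (default 1000);
#'   * `covariate_set`: `"core"` (default) or `"extended"`.
#' @return invisibly, a named list of the output file paths and in-memory
#'   results.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) fail("config$out_dir is required")
  if (is.null(config$seed)) fail("config$seed is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dii_params <- if (is.null(config$dii_params)) dii_reference()
                else load_dii_params(config$dii_params)
  dobs_spec <- if (is.null(config$dobs_spec)) dobs_reference()
               else load_dobs_spec(config$dobs_spec)
  covset <- if (is.null(config$covariate_set)) "core" else config$covariate_set
  rcs_k <- if (is.null(config$rcs_k)) 4 else config$rcs_k
  n_draws <- if (is.null(config$n_draws)) 1000 else config$n_draws
  do_med <- if (is.null(config$mediation)) TRUE else isTRUE(config$mediation)

  data <- run_stage("input", {
    if (is.null(config$input)) {
      cc <- config$cohort_config
      if (is.null(cc)) cc <- list()
      if (is.null(cc$seed)) cc$seed <- config$seed
      generate_cohort(do.call(cohort_config, cc))$data
    } else if (is.character(config$input)) {
      read_cohort(config$input, config$var_map)
    } else config$input
  })

  cohort <- run_stage("exclusions", apply_exclusions(
    data, components = union(dii_params$component, dobs_spec$component)))
  adf <- cohort$records
  if (nrow(adf) < 30L) fail("pipeline stage `exclusions` failed: fewer than 30 analytic records")

  adf <- run_stage("scoring", score_cohort(adf, dii_params, dobs_spec))
  design <- run_stage("design", survey_design(adf$survey_weight))

  adf <- run_stage("outcome_coding", {
    adf$obesity <- classify_obesity(adf$bmi)
    adf$high_wc_class <- classify_wc(adf$wc)
    for (v in c("shbg", "tt", "e2"))
      adf[[paste0("high_", v)]] <- as.integer(
        dichotomize_at_median(adf[[v]], adf$survey_weight))
    adf
  })

  covs <- run_stage("covariates", model_covariates(adf, covset))
  mdf <- cbind(adf, covs[, setdiff(names(covs), names(adf)), drop = FALSE])
  cov_names <- if (covset == "extended") extended_covariates else core_covariates

  paths <- list()
  wr <- function(tab, name) {
    p <- file.path(out_dir, name)
    write.csv(tab, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(cohort$exclusion_log, "exclusions.csv")

  run_stage("descriptives", {
    vars <- c("age", "dii", "dobs", "bmi", "wc", "shbg", "race", "education",
              "smoking", "diet_class")
    wr(table_one(mdf, vars, group = NULL, design), "table1_overall.csv")
    mdf$infertility_group <- factor(ifelse(mdf$infertility == 1,
                                           "infertile", "fertile"))
    t1 <- lapply(levels(mdf$obesity), function(g) {
      i <- mdf$obesity == g
      tab <- table_one(mdf[i, ], c("dii", "dobs", "diet_class"),
                       group = "infertility_group",
                       design = design_subset(design, i))
      cbind(stratum = g, tab)
    })
    wr(do.call(rbind, t1), "table1_by_obesity.csv")
  })

  fits_logistic <- run_stage("logistic_models", {
    exposures <- c("dii", "dii_tertile", "dobs", "dobs_tertile", "diet_class",
                   "bmi", "wc")
    outcomes <- c("infertility", "high_shbg")
    rows <- list()
    for (y in outcomes) for (x in exposures) {
      fml <- as.formula(paste(y, "~", paste(c(x, cov_names), collapse = " + ")))
      f <- fit_weighted_glm(fml, mdf, design)
      ct <- f$coefficients
      ct <- ct[grepl(paste0("^", x), ct$term), , drop = FALSE]
      if (nrow(ct))
        rows[[length(rows) + 1L]] <- cbind(outcome = y, exposure = x, ct)
    }
    do.call(rbind, rows)
  })
  wr(fits_logistic, "logistic_models.csv")

  fits_linear <- run_stage("linear_models", {
    outcomes <- c("shbg", "tt", "e2", "bmi", "wc")
    exposures <- c("dii", "dobs", "diet_class", "bmi", "wc")
    rows <- list()
    for (y in outcomes) for (x in exposures) {
      if (y %in% c("bmi", "wc") && x %in% c("bmi", "wc")) next
      fml <- as.formula(paste(y, "~", paste(c(x, cov_names), collapse = " + ")))
      f <- fit_weighted_lm(fml, mdf, design)
      ct <- f$coefficients
      ct <- ct[grepl(paste0("^", x), ct$term), , drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(outcome = y, exposure = x, ct)
    }
    do.call(rbind, rows)
  })
  wr(fits_linear, "linear_models.csv")

  rcs_out <- run_stage("rcs", {
    combos <- expand.grid(outcome = c("infertility", "high_shbg"),
                          exposure = c("dii", "dobs"),
                          stringsAsFactors = FALSE)
    pv <- list(); grids <- list()
    for (i in seq_len(nrow(combos))) {
      r <- rcs_logistic(combos$outcome[i], combos$exposure[i], cov_names,
                        mdf, design, k = rcs_k)
      pv[[i]] <- data.frame(outcome = combos$outcome[i],
                            exposure = combos$exposure[i],
                            p_overall = r$p_overall,
                            p_nonlinear = r$p_nonlinear,
                            knots = paste(signif(r$knots, 6), collapse = ";"))
      grids[[i]] <- cbind(outcome = combos$outcome[i],
                          exposure = combos$exposure[i], r$curve)
    }
    wr(do.call(rbind, pv), "rcs_pvalues.csv")
    wr(do.call(rbind, grids), "rcs_curves.csv")
    pv
  })

  if (do_med) {
    med_tab <- run_stage("mediation", {
      sd_dii <- sd(mdf$dii); sd_dobs <- sd(mdf$dobs)
      mdf$dii_std <- (mdf$dii - mean(mdf$dii)) / sd_dii
      mdf$dobs_std <- (mdf$dobs - mean(mdf$dobs)) / sd_dobs
      mdf$anti_diet <- ifelse(
        mdf$diet_class == "anti_inflammatory_anti_oxidative", 1L,
        ifelse(mdf$diet_class == "pro_inflammatory_pro_oxidative", 0L,
               NA_integer_))
      res <- list()
      i <- 0L
      for (x in c("dii_std", "dobs_std", "anti_diet")) for (m in c("bmi", "wc")) {
        i <- i + 1L
        res[[i]] <- mediate_effects("infertility", x, m, cov_names, mdf,
                                    design, n_draws = n_draws,
                                    seed = config$seed + i)
      }
      mediation_table(res)
    })
    wr(med_tab, "mediation.csv")
  }

  manifest <- list(
    package = "dietscores",
    version = as.character(utils::packageVersion("dietscores")),
    seed = config$seed, covariate_set = covset, rcs_k = rcs_k,
    n_draws = n_draws, mediation = do_med,
    n_input = nrow(data), n_analytic = nrow(adf),
    outputs = names(paths))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- mp

  invisible(list(paths = paths, analytic = mdf, exclusions = cohort$exclusion_log,
                 logistic = fits_logistic, linear = fits_linear,
                 rcs = rcs_out))
}
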
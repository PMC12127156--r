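test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(path_a = NA), "path_a")
  bad <- default_covariate_spec()
  bad$race_probs <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(cohort_config(covariate_spec = bad), "race_probs")
  spec <- default_intake_spec()
  spec$sdlog[1] <- 0
  expect_error(cohort_config(intake_spec = spec), "sdlog")
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_config(n_participants = 150, seed = 99))
  b <- generate_cohort(cohort_config(n_participants = 150, seed = 99))
  expect_identical(a$data, b$data)
  c <- generate_cohort(cohort_config(n_participants = 150, seed = 100))
  expect_false(identical(a$data, c$data))
})

test_that("generated cohorts satisfy the record invariants", {
  co <- small_cohort(n = 500, seed = 41, design_blocks = TRUE)
  df <- co$data
  comps <- default_intake_spec()$component
  expect_true(all(df$survey_weight > 0))
  expect_true(all(as.matrix(df[, setdiff(comps, "alcohol")]) > 0))
  expect_true(all(df$alcohol >= 0))
  expect_true(any(df$alcohol == 0))          # nondrinkers exist
  expect_true(all(df$infertility %in% 0:1))
  expect_true(all(df$bmi > 0) && all(df$wc > 0))
  expect_true(all(df$age >= 20 & df$age <= 45))
  expect_true(all(c("stratum", "psu") %in% names(df)))
  expect_true(any(is.na(df$pir)))            # PIR missingness planted
})

test_that("null-path cohorts decouple score, mediator, and outcome", {
  co <- generate_cohort(cohort_config(n_participants = 50000, seed = 43,
                                      path_a = 0, path_b = 0, path_c = 0,
                                      outcome_intercept = qlogis(0.125)))
  df <- co$data
  d <- survey_design(df$survey_weight)
  prev <- weighted_mean_se(df$infertility, d)
  # binomial sampling oracle: SE of the weighted mean of iid Bernoulli(1/8)
  wn <- df$survey_weight / sum(df$survey_weight)
  mc_se <- sqrt(sum(wn^2) * 0.125 * 0.875)
  expect_lt(abs(prev["mean"] - 0.125), 3 * mc_se)
  # correlation between score and mediator within 3 SEs of 0
  r <- cor(df$diet_score, df$bmi)
  expect_lt(abs(r), 3 / sqrt(nrow(df)))
})

test_that("the proportion-mediated oracle matches closed-form limits", {
  co_b0 <- generate_cohort(cohort_config(n_participants = 200, seed = 44,
                                         path_b = 0))
  expect_equal(as.numeric(true_proportion_mediated(co_b0)), 0)

  co_c0 <- generate_cohort(cohort_config(n_participants = 200, seed = 45,
                                         path_c = 0, path_a = 0.8,
                                         path_b = 0.08))
  expect_equal(as.numeric(true_proportion_mediated(co_c0, n_draws = 2e5)), 1,
               tolerance = 0.01)

  co_00 <- generate_cohort(cohort_config(n_participants = 200, seed = 46,
                                         path_a = 0, path_b = 0, path_c = 0))
  expect_error(true_proportion_mediated(co_00), "undefined")
})

test_that("oracle agrees with a brute-force counterfactual simulation", {
  co <- generate_cohort(cohort_config(n_participants = 200, seed = 47))
  tr <- co$truth
  pm <- true_proportion_mediated(co, n_draws = 1e6, seed = 2)
  # independent brute force: simulate the four potential outcomes directly
  set.seed(1234)
  N <- 1e6
  ms <- tr$mediator_spec
  e <- rnorm(N, 0, ms$bmi_sd)
  pr <- function(t, tm) {
    m <- ms$bmi_base + tr$path_a * tm + e
    mean(plogis(tr$outcome_intercept + tr$path_c * t + tr$path_b * m))
  }
  acme <- ((pr(1, 1) - pr(1, 0)) + (pr(0, 1) - pr(0, 0))) / 2
  total <- pr(1, 1) - pr(0, 0)
  expect_equal(as.numeric(pm), acme / total, tolerance = 0.01)
  expect_true(pm >= 0 && pm <= 1)
})

test_that("proportion mediated rises with the mediator path", {
  grid <- c(0.3, 0.8, 1.5)
  pms <- vapply(grid, function(a) {
    co <- generate_cohort(cohort_config(n_participants = 100, seed = 48,
                                        path_a = a, path_b = 0.08,
                                        path_c = 0.15))
    as.numeric(true_proportion_mediated(co, n_draws = 2e5, seed = 3))
  }, numeric(1))
  expect_true(all(diff(pms) > 0))
})
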
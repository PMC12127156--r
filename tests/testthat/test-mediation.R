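med_fixture <- function(n = 3000, seed = 50, ...) {
  co <- generate_cohort(cohort_config(n_participants = n, seed = seed, ...))
  list(df = co$data, d = survey_design(co$data$survey_weight), co = co)
}

test_that("mediation results are deterministic given the seed and decompose", {
  fx <- med_fixture(n = 1200, seed = 51)
  m1 <- mediate_effects("infertility", "diet_score", "bmi", "age",
                        fx$df, fx$d, n_draws = 200, seed = 7)
  m2 <- mediate_effects("infertility", "diet_score", "bmi", "age",
                        fx$df, fx$d, n_draws = 200, seed = 7)
  expect_identical(m1$acme, m2$acme)
  expect_identical(m1$total_effect, m2$total_effect)
  # decomposition holds exactly for the point estimates (shared draws)
  expect_equal(m1$total_effect$estimate, m1$acme$estimate + m1$ade$estimate,
               tolerance = 1e-12)
  expect_equal(m1$scale, "risk_difference")
  expect_error(mediate_effects("infertility", "diet_score", "bmi", "age",
                               fx$df, fx$d, n_draws = 200), "seed")
  expect_error(mediate_effects("infertility", "diet_score", "bmi", "age",
                               fx$df, fx$d, n_draws = 50, seed = 1), "100")
})

test_that("no mediator path means no mediated effect", {
  fx <- med_fixture(n = 4000, seed = 52, path_a = 0)
  m <- mediate_effects("infertility", "diet_score", "bmi", "age",
                       fx$df, fx$d, n_draws = 300, seed = 8)
  # point estimate near zero and a small share of the (direct) effect;
  # nominal CI coverage under the null is tested over many replicates in the
  # calibration suite, not on a single realization
  expect_lt(abs(m$acme$estimate), 0.01)
  expect_lt(abs(m$acme$estimate), abs(m$ade$estimate) / 2)
})

test_that("a fully mediated effect yields proportion near 1", {
  fx <- med_fixture(n = 8000, seed = 53, path_c = 0, path_a = 1.2,
                    path_b = 0.1)
  m <- mediate_effects("infertility", "diet_score", "bmi", "age",
                       fx$df, fx$d, n_draws = 300, seed = 9)
  expect_true(m$stable_total)
  expect_true(m$prop_mediated$conf_low <= 1 &&
              1 <= m$prop_mediated$conf_high + 0.15)
  expect_gt(m$prop_mediated$estimate, 0.6)
})

test_that("linear-linear ACME matches the product-of-coefficients oracle", {
  fx <- med_fixture(n = 8000, seed = 54)
  # continuous SHBG outcome: generating ACME = path_a * beta_mediator
  truth_ab <- fx$co$truth$path_a * fx$co$truth$shbg_model$beta_mediator
  m <- mediate_effects("shbg", "diet_score", "bmi", "age", fx$df, fx$d,
                       n_draws = 400, seed = 10)
  expect_equal(m$scale, "mean_difference")
  expect_true(m$acme$conf_low <= truth_ab && truth_ab <= m$acme$conf_high)
  # Baron-Kenny closed form on the same sample as an independent oracle
  a_hat <- coef(lm(bmi ~ diet_score + age, fx$df,
                   weights = fx$df$survey_weight))["diet_score"]
  b_hat <- coef(lm(shbg ~ diet_score + bmi + age, fx$df,
                   weights = fx$df$survey_weight))["bmi"]
  expect_equal(m$acme$estimate, unname(a_hat * b_hat), tolerance = 0.06)
})

test_that("an unstable total effect flags the proportion instead of reporting it", {
  fx <- med_fixture(n = 800, seed = 55, path_a = 0, path_b = 0, path_c = 0)
  m <- mediate_effects("infertility", "diet_score", "bmi", "age",
                       fx$df, fx$d, n_draws = 200, seed = 11)
  expect_false(m$stable_total)
  expect_true(is.na(m$prop_mediated$conf_low))
})

test_that("mediation_table lays out one row per triple with percent mediated", {
  fx <- med_fixture(n = 1500, seed = 56)
  res <- list()
  for (m in c("bmi", "wc"))
    for (x in c("diet_score", "dii_proxy")) {
      fx$df$dii_proxy <- fx$df$diet_score + rnorm(nrow(fx$df), 0, 0.3)
      res[[length(res) + 1L]] <- mediate_effects(
        "infertility", x, m, "age", fx$df, fx$d, n_draws = 150,
        seed = 12 + length(res))
    }
  tab <- mediation_table(res)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$pct_mediated, 100 * vapply(res, function(r)
    r$prop_mediated$estimate, numeric(1)))
  expect_true(all(c("acme", "ade", "total", "pct_mediated", "acme_sig")
                  %in% names(tab)))
})
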
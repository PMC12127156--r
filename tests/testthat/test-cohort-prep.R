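planted_raw_table <- function() {
  base <- small_cohort(n = 60, seed = 21)$data
  # plant violations: 3 males, 4 out-of-age, 2 missing diet, 3 missing outcome
  base$sex[1:3] <- "male"
  base$age[4:6] <- c(19, 46, 55)
  base$age[7] <- 17            # male rows removed first; these are females
  base$fiber[8:9] <- NA
  base$shbg[10] <- NA; base$bmi[11] <- NA; base$infertility[12] <- NA
  base
}

test_that("exclusion filters run in order and log planted counts", {
  raw <- planted_raw_table()
  res <- apply_exclusions(raw)
  log <- res$exclusion_log
  expect_equal(log$step, c("male", "age_out_of_range", "missing_diet_component",
                           "missing_outcome_or_mediator"))
  expect_equal(log$n_removed, c(3L, 4L, 2L, 3L))
  expect_equal(sum(log$n_removed), nrow(raw) - nrow(res$records))
  expect_equal(log$n_remaining[4], nrow(res$records))

  # idempotence: a second pass removes nothing
  res2 <- apply_exclusions(res$records)
  expect_equal(res2$exclusion_log$n_removed, rep(0L, 4))
  expect_equal(nrow(res2$records), nrow(res$records))

  # age 19 female excluded at the age step, eligible record retained
  expect_false(19 %in% res$records$age)
  expect_true(all(res$records$age >= 20 & res$records$age <= 45))
})

test_that("HOMA-IR follows the insulin-glucose formula", {
  expect_equal(homa_ir(22.5, 1.0), 1.0)
  expect_equal(homa_ir(10, 5.0), 10 * 5 / 22.5)
  expect_equal(homa_ir(0, 7), 0)
  expect_error(homa_ir(-1, 5), "non-negative")
})

test_that("obesity and high-WC thresholds are boundary inclusive", {
  expect_equal(as.character(classify_obesity(c(30, 29.99, 35, 18))),
               c("obese", "nonobese", "obese", "nonobese"))
  expect_equal(as.character(classify_wc(c(88, 87.99, 100))),
               c("high_wc", "normal", "high_wc"))
  expect_error(classify_obesity(0), "positive")
  expect_error(classify_wc(-2), "positive")
  # monotone step functions
  b <- seq(15, 45, by = 0.5)
  expect_true(all(diff(as.integer(classify_obesity(b))) >= 0))
})

test_that("median dichotomization matches the weighted-median oracle", {
  d <- dichotomize_at_median(1:4)
  expect_equal(attr(d, "cutpoint"), 2.5)
  expect_equal(as.integer(d), c(0L, 0L, 1L, 1L))

  # brute-force oracle on random values/weights: labels = value > cutpoint,
  # and the cutpoint splits weight so neither side exceeds half + tie mass
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(25); w <- rgamma(25, 2, 2)
    d <- dichotomize_at_median(x, w)
    cut <- attr(d, "cutpoint")
    expect_equal(as.integer(d), as.integer(x > cut))
    expect_lte(sum(w[x > cut]) / sum(w), 0.5 + 1e-9)
    # doubling the weights changes nothing
    expect_equal(as.integer(dichotomize_at_median(x, 2 * w)), as.integer(d))
  }

  # all weight on one observation
  d1 <- dichotomize_at_median(c(5, 1, 9), c(1e9, 1e-9, 1e-9))
  expect_equal(attr(d1, "cutpoint"), 5)

  # equal weights split a tie-free even sample exactly in half
  set.seed(9)
  x <- rnorm(40)
  expect_equal(sum(dichotomize_at_median(x)), 20L)
  expect_error(dichotomize_at_median(rep(1, 5)), "identical")
})

test_that("covariate coding keeps PIR missing as a category and is boundary-correct", {
  df <- data.frame(
    age = c(25, 40), race = c("nonhispanic_white", "other"),
    education = c("high_school", "college_graduate"),
    marital = c("married_or_partner", "live_alone"),
    pir = c(NA, 0.5), smoking = c("never", "current"),
    physical_activity = c(600, 599.9), total_energy = c(1800, 2200))
  cc <- code_covariates(df)
  expect_equal(as.character(cc$pir_cat), c("miss", "lt1"))
  expect_equal(as.character(cc$pa_cat), c("ge600", "lt600"))
  expect_equal(as.character(cc$smoking), c("never", "current"))
  expect_equal(levels(cc$pir_cat), c("lt1", "ge1", "miss"))
  df$race[1] <- "martian"
  expect_error(code_covariates(df), "unknown race")
})

test_that("cohort files round-trip through CSV", {
  co <- small_cohort(n = 25, seed = 5)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(paths[["data"]])
  expect_equal(nrow(back), 25L)
  expect_equal(back$bmi, co$data$bmi, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$path_a, co$truth$path_a)
  # variable-name mapping
  renamed <- read_cohort(paths[["data"]], var_map = c(bmi = "body_mass_index"))
  expect_true("body_mass_index" %in% names(renamed))
})
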
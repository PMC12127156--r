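test_that("equal-weight fits reduce to classical GLM/LM to 1e-8", {
  set.seed(20)
  n <- 300
  df <- data.frame(x = rnorm(n), z = rnorm(n))
  df$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * df$x))
  df$yl <- 1 + 2 * df$x - df$z + rnorm(n)
  d <- equal_design(n)

  f <- fit_weighted_glm(y ~ x + z, df, d)
  classical <- glm(y ~ x + z, family = binomial(), data = df)
  expect_equal(coef(f$fit), coef(classical), tolerance = 1e-8)

  fl <- fit_weighted_lm(yl ~ x + z, df, d)
  expect_equal(coef(fl$fit), coef(lm(yl ~ x + z, data = df)), tolerance = 1e-10)
})

test_that("the 2x2 logistic OR equals the closed-form cross-product ratio", {
  df <- data.frame(exposed = rep(c(1, 0), each = 100),
                   y = c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85)))
  f <- fit_weighted_glm(y ~ exposed, df, equal_design(200))
  or_closed <- (30 * 85) / (70 * 15)
  expect_equal(f$coefficients$or[f$coefficients$term == "exposed"],
               or_closed, tolerance = 1e-8)
  expect_equal(or_closed, 2.428571, tolerance = 1e-6)
})

test_that("weight semantics: rescaling and frequency-duplication invariances", {
  set.seed(21)
  n <- 200
  df <- data.frame(x = rnorm(n))
  df$y <- rbinom(n, 1, plogis(0.5 * df$x))
  w <- rgamma(n, 2, 2)
  f1 <- fit_weighted_glm(y ~ x, df, survey_design(w))
  f2 <- fit_weighted_glm(y ~ x, df, survey_design(2 * w))
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-8)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-6)

  # one observation with weight 2 = the same observation duplicated
  df2 <- data.frame(x = c(df$x, df$x[1]), y = c(df$y, df$y[1]))
  wdup <- c(w, w[1]); wdup2 <- w; wdup2[1] <- w[1] * 2
  fa <- fit_weighted_lm(y ~ x, df, survey_design(wdup2))
  fb <- fit_weighted_lm(y ~ x, df2, survey_design(wdup))
  expect_equal(coef(fa$fit), coef(fb$fit), tolerance = 1e-10)
})

test_that("weighted least squares recovers a planted slope", {
  set.seed(22)
  n <- 4000
  df <- data.frame(x = rnorm(n))
  df$y <- 2 * df$x + rnorm(n)
  f <- fit_weighted_lm(y ~ x, df, survey_design(rgamma(n, 2, 2)))
  est <- f$coefficients[f$coefficients$term == "x", ]
  expect_equal(est$estimate, 2, tolerance = 0.1)
  expect_true(est$conf_low < 2 && 2 < est$conf_high)
})

test_that("errors: non-binary outcome, rank deficiency, missing reference", {
  df <- data.frame(x = rnorm(20), y = rnorm(20))
  expect_error(fit_weighted_glm(y ~ x, df, equal_design(20)), "binary")
  df$x2 <- df$x
  expect_error(fit_weighted_lm(y ~ x + x2, df, equal_design(20)),
               "rank-deficient")
})

test_that("tertile contrasts report OR versus the reference tertile", {
  set.seed(23)
  co <- small_cohort(n = 2000, seed = 23, path_a = 0, path_b = 0,
                     path_c = 0.62, outcome_intercept = qlogis(0.25))$data
  co$t3 <- factor(paste0("T", assign_tertiles(co$diet_score)))
  d <- survey_design(co$survey_weight)
  f <- fit_weighted_glm(infertility ~ t3 + age, co, d)
  ct <- tertile_contrasts(f, "t3")
  expect_equal(ct$level, c("T1", "T2", "T3"))
  expect_equal(ct$or[1], 1)
  # planted positive log-OR along the score: T3 above T1, CI excludes 1
  expect_gt(ct$or[3], ct$or[1])
  expect_gt(ct$or_low[3], 1)
  expect_error(tertile_contrasts(f, "age"), "factor")
})

test_that("CI coverage is near nominal for both families", {
  set.seed(24)
  n <- 400
  cover_glm <- cover_lm <- logical(250)
  for (i in seq_len(250)) {
    x <- rnorm(n); w <- 0.25 + rgamma(n, 4, 4 / 0.75)
    y <- rbinom(n, 1, plogis(-1 + 0.4 * x))
    f <- fit_weighted_glm(y ~ x, data.frame(x = x, y = y), survey_design(w))
    e <- f$coefficients[2, ]
    cover_glm[i] <- e$conf_low <= 0.4 && 0.4 <= e$conf_high
    yl <- 1 + 0.7 * x + rnorm(n)
    fl <- fit_weighted_lm(yl ~ x, data.frame(x = x, yl = yl), survey_design(w))
    el <- fl$coefficients[2, ]
    cover_lm[i] <- el$conf_low <= 0.7 && 0.7 <= el$conf_high
  }
  expect_gt(mean(cover_glm), 0.91)
  expect_lt(mean(cover_glm), 0.985)
  expect_gt(mean(cover_lm), 0.91)
  expect_lt(mean(cover_lm), 0.985)
})
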
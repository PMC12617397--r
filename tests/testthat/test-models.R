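test_that("Rubin pooling matches hand arithmetic", {
  p <- pool_rubin(c(1, 2, 3), c(1, 1, 1), df_complete = 100)
  expect_equal(p$estimate, 2)
  expect_equal(p$within, 1)
  expect_equal(p$between, 1)
  expect_equal(p$total, 1 + (4 / 3) * 1)

  # degenerate pooling: m identical fits reduce to the single fit
  pd <- pool_rubin(rep(1.0, 4), rep(0.2^2, 4), df_complete = 50)
  expect_equal(pd$estimate, 1.0)
  expect_equal(pd$between, 0)
  expect_equal(pd$total, 0.04)
  expect_equal(pd$se, 0.2)
  expect_equal(pd$df, 50)

  expect_error(pool_rubin(1, 1, 10), "at least 2")
})

test_that("pooled variance dominates the within-imputation variance", {
  set.seed(42)
  for (k in 1:50) {
    m <- sample(2:8, 1)
    est <- rnorm(m)
    v <- runif(m, 0.1, 2)
    p <- pool_rubin(est, v, df_complete = sample(10:500, 1))
    expect_gte(p$total, p$within)
    expect_gte(p$between, 0)
    expect_gt(p$df, 0)
  }
})

test_that("ICC and conditional R2 follow their variance decompositions", {
  expect_equal(compute_icc(0, 3), 0)
  expect_equal(compute_icc(1, 3), 0.25)
  expect_error(compute_icc(-1, 3), ">= 0")
  set.seed(2)
  for (k in 1:20) {
    s2c <- runif(1, 0, 5)
    s2e <- runif(1, 0.1, 5)
    icc <- compute_icc(s2c, s2e)
    expect_gte(icc, 0)
    expect_lte(icc, 1)
  }
})

test_that("mixed model reduces to OLS in the zero cluster-variance limit", {
  set.seed(11)
  n <- 1500
  d <- data.frame(
    country = factor(rep(c("A", "B", "C"), each = n / 3)),
    log_rmssd = rnorm(n), age = runif(n, 13, 15),
    gender = factor(sample(c("f", "m"), n, TRUE)),
    bmi = rnorm(n, 20, 3),
    device = factor(sample(c("ECG", "PPG"), n, TRUE))
  )
  d$y <- 5 + 1.5 * d$log_rmssd + 0.2 * d$bmi + rnorm(n)
  fit <- fit_lmm(d, model_spec("y"))
  expect_true(fit$singular)
  expect_lt(fit$icc, 1e-6)
  ols <- lm(y ~ log_rmssd + age + gender + bmi + device, data = d)
  got <- fit$coefficients$estimate
  names(got) <- fit$coefficients$term
  expect_equal(got[names(coef(ols))], coef(ols), tolerance = 1e-6)
})

test_that("estimated cluster variance grows with true cluster separation", {
  set.seed(12)
  n <- 300
  base <- data.frame(country = factor(rep(c("A", "B", "C"), each = n / 3)),
                     x = rnorm(n))
  s2 <- vapply(c(0, 2, 5, 10), function(shift) {
    d <- base
    d$y <- shift * (as.integer(d$country) - 2) + d$x + rnorm(n)
    f <- lmerTest::lmer(y ~ x + (1 | country), data = d,
                        control = lme4::lmerControl(calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
    as.data.frame(lme4::VarCorr(f))$vcov[1]
  }, numeric(1))
  expect_true(all(diff(s2) > 0))
})

test_that("conditional R2 rises when a predictive covariate is added", {
  set.seed(13)
  co <- simulate_cohort(n_per_country = 200, beta_logrmssd = 0,
                        covariate_effects = c(bmi = 1.5), seed = 14)
  f_null <- fit_lmm(co, model_spec("outcome", fixed = c("log_rmssd", "age")))
  f_bmi <- fit_lmm(co, model_spec("outcome",
                                  fixed = c("log_rmssd", "age", "bmi")))
  expect_gt(conditional_r2(f_bmi), conditional_r2(f_null))
})

test_that("Satterthwaite df approaches residual df on large balanced data", {
  set.seed(15)
  n <- 999
  d <- data.frame(country = factor(rep(c("A", "B", "C"), each = n / 3)),
                  log_rmssd = rnorm(n))
  d$y <- 2 + 0.5 * d$log_rmssd +
    rep(rnorm(3, 0, 2), each = n / 3) + rnorm(n)
  fit <- fit_lmm(d, model_spec("y", fixed = "log_rmssd"))
  df <- fit$coefficients$df[fit$coefficients$term == "log_rmssd"]
  expect_lt(abs(df - (n - 2)) / (n - 2), 0.05)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.0007, 7), 0.0049)
  expect_equal(bonferroni_adjust(0.5, 7), 1.0)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), 1), c(0.01, 0.2))
  expect_error(bonferroni_adjust(1.2, 7), "0, 1")
  expect_error(bonferroni_adjust(0.1, 0), ">= 1")
})

test_that("country GLM matches the pooled fixed effects without cluster variance", {
  co <- simulate_cohort(n_per_country = 400, beta_logrmssd = 1,
                        country_intercept_sd = 0, seed = 16)
  one <- droplevels(co[co$country == "Nepal", ])
  glm_fit <- fit_country_glm(co, "Nepal", model_spec("outcome"))
  b_glm <- glm_fit$coefficients$estimate[
    glm_fit$coefficients$term == "log_rmssd"]
  lmm_one <- suppressWarnings(fit_lmm(transform(one, country = factor(
    rep(c("x", "y"), length.out = nrow(one)))), model_spec("outcome")))
  b_lmm <- lmm_one$coefficients$estimate[
    lmm_one$coefficients$term == "log_rmssd"]
  expect_equal(b_glm, b_lmm, tolerance = 1e-3)

  # Colombia-like subsets use a single device: coefficient must be absent
  co$device[co$country == "Colombia"] <- "ECG_chest"
  expect_warning(g2 <- fit_country_glm(co, "Colombia", model_spec("outcome")),
                 "device")
  expect_false(any(grepl("device", g2$coefficients$term)))
  expect_true("device" %in% g2$dropped)
  expect_true(all(g2$coefficients$p_bonferroni >= g2$coefficients$p))
})

test_that("single-country GLM rejection rate is near alpha under the null", {
  reps <- 200
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    co <- simulate_cohort(n_per_country = 60, beta_logrmssd = 0,
                          seed = 6000 + r)
    g <- suppressWarnings(fit_country_glm(co, "Nepal", model_spec("outcome")))
    p <- g$coefficients$p[g$coefficients$term == "log_rmssd"]
    rej[r] <- p < 0.05
  }
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})
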
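test_that("a noiseless log-log relation is recovered exactly", {
  d <- toy_regression_data(n = 50, beta = 0.1, noise_sd = 0)
  fit <- suppressWarnings(
    fit_elasticity(d$biometrics, d$measures, dependent = "bmi",
                   tool = "basket")
  )
  expect_equal(unname(fit$beta), 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n, 50)
})

test_that("the true elasticity is recovered within 2 robust SEs on synthetic cohorts", {
  for (s in c(101, 202, 303)) {
    cohort <- generate_cohort(cohort_params(seed = s))
    recall0 <- generate_recall(cohort, day_noise_sd = 0, underreport_slope = 0)
    pids <- cohort$participants$participant_id
    cal <- vapply(pids, function(p) {
      recall_daily_nutrients(recall0[[p]])[["calories"]]
    }, numeric(1))
    measures <- data.frame(participant_id = pids, tool = "recall",
                           calories = cal, stringsAsFactors = FALSE)
    bio <- cohort$participants[, c("participant_id", "weight_kg", "bmi",
                                   "waist_in")]
    fit <- fit_elasticity(bio, measures, study_covariates(cohort),
                          dependent = "bmi", tool = "recall")
    expect_lt(abs(unname(fit$beta) - 0.095), 2 * unname(fit$robust_se))
  }
})

test_that("the elasticity is invariant to rescaling calories", {
  d <- toy_regression_data(n = 80, beta = 0.08, noise_sd = 0.05, seed = 4)
  f1 <- fit_elasticity(d$biometrics, d$measures, dependent = "bmi")
  d$measures$calories <- d$measures$calories * 7
  f2 <- fit_elasticity(d$biometrics, d$measures, dependent = "bmi")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-10)
})

test_that("OLS residuals are orthogonal to all regressors", {
  study <- simulate_study(cohort_params(n_participants = 120), seed = 8)
  fit <- fit_elasticity(study$biometrics, study$measures, study$covariates,
                        dependent = "weight", tool = "basket")
  X <- model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(X, residuals(fit$fit)))), 1e-8)
})

test_that("stars follow the two-sided robust test at 10/5/1 percent", {
  d <- toy_regression_data(n = 200, beta = 0.3, noise_sd = 0.02, seed = 5)
  fit <- fit_elasticity(d$biometrics, d$measures, dependent = "bmi")
  expect_identical(unname(fit$stars), "***")
  z <- abs(fit$beta / fit$robust_se)
  expect_lt(2 * pnorm(-z), 0.01)
})

test_that("degenerate designs and invalid inputs are rejected", {
  d <- toy_regression_data(n = 40, beta = 0.1, noise_sd = 0.1, seed = 2)
  d$measures$calories <- 2000 # constant regressor
  expect_error(fit_elasticity(d$biometrics, d$measures, dependent = "bmi"),
               "collinear")

  d <- toy_regression_data(n = 40, beta = 0.1, noise_sd = 0.1, seed = 2)
  d$biometrics$bmi[3] <- -1
  expect_error(fit_elasticity(d$biometrics, d$measures, dependent = "bmi"),
               "P003")

  d <- toy_regression_data(n = 40, beta = 0.1, noise_sd = 0.1, seed = 2)
  d$measures$calories[5] <- 0
  expect_warning(
    fit <- fit_elasticity(d$biometrics, d$measures, dependent = "bmi"),
    "P005"
  )
  expect_equal(fit$n, 39)

  cov_na <- data.frame(participant_id = d$biometrics$participant_id,
                       age = c(NA, rnorm(39, 40, 10)))
  expect_error(
    suppressWarnings(fit_elasticity(d$biometrics, d$measures, cov_na,
                                    dependent = "bmi")),
    "age"
  )
})

test_that("several calorie measures can enter one regression", {
  study <- simulate_study(cohort_params(n_participants = 150), seed = 12)
  fit <- fit_elasticity(study$biometrics, study$measures, study$covariates,
                        dependent = "bmi", tool = c("basket", "recall", "ffq"))
  expect_named(fit$beta, c("basket", "recall", "ffq"))
  expect_length(fit$robust_se, 3)
})
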
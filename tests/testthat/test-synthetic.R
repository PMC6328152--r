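test_that("the full pipeline is deterministic under a fixed seed", {
  s1 <- simulate_study(cohort_params(n_participants = 60), seed = 33)
  s2 <- simulate_study(cohort_params(n_participants = 60), seed = 33)
  expect_identical(s1$cohort$participants, s2$cohort$participants)
  expect_identical(s1$measures, s2$measures)
  expect_identical(s1$exposures, s2$exposures)
  s3 <- simulate_study(cohort_params(n_participants = 60), seed = 34)
  expect_false(identical(s1$measures, s3$measures))
})

test_that("parameter invariants are validated", {
  expect_error(cohort_params(n_participants = 400, n_sessions = 20,
                             max_session_size = 18), "capacity")
  expect_error(cohort_params(day_noise_sd = -1), "non-negative")
  expect_error(cohort_params(budget = 0), "budget")
  expect_error(cohort_params(income_probs = rep(0.2, 5)), "income")
})

test_that("with all noise off the log biometric is affine in latent calories", {
  prm <- cohort_params(
    n_participants = 40,
    biometric_noise_sd = c(weight = 0, bmi = 0, waist = 0),
    male_effect = c(weight = 0, bmi = 0, waist = 0),
    age_effect = c(weight = 0, bmi = 0, waist = 0),
    seed = 2
  )
  cohort <- generate_cohort(prm)
  p <- cohort$participants
  fit <- lm(log(bmi) ~ latent_log_calories, data = p)
  expect_equal(unname(coef(fit)[2]), 0.095, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("default cohorts land on the target mean BMI and dispersion pattern", {
  cohort <- generate_cohort(cohort_params(seed = 19))
  p <- cohort$participants
  se <- 5.36 / sqrt(255)
  expect_lt(abs(mean(p$bmi) - 25.36), 3 * se)
  # dispersion is larger above BMI 25 than below, as in the study population
  expect_gt(sd(p$bmi[p$bmi >= 25]), sd(p$bmi[p$bmi < 25]))
  # session structure respects capacity
  sizes <- table(p$session_id)
  expect_lte(max(sizes), 18)
  expect_equal(sum(sizes), 255)
})

test_that("generated baskets are feasible and track the latent propensity", {
  cohort <- generate_cohort(cohort_params(seed = 23))
  catalog <- default_catalog()
  baskets <- generate_baskets(cohort, catalog)
  costs <- vapply(baskets, function(b) total_cost(b, catalog), integer(1))
  expect_true(all(costs <= 3000))
  expect_true(all(vapply(baskets, function(b) checkout(b, catalog)$accepted,
                         logical(1))))
  kcal <- vapply(baskets, function(b) nutrient_totals(b, catalog)[["calories"]],
                 numeric(1))
  expect_gt(cor(kcal, cohort$participants$latent_log_calories), 0.5)
})

test_that("an unaffordable catalog raises a generation error", {
  cohort <- generate_cohort(cohort_params(n_participants = 10, budget = 50L,
                                          seed = 3))
  expect_error(generate_baskets(cohort, tiny_catalog()), "affordable")
})

test_that("recall recovers latent calories exactly in the identity regime", {
  cohort <- generate_cohort(cohort_params(n_participants = 30, seed = 6))
  entries <- generate_recall(cohort, day_noise_sd = 0, underreport_slope = 0)
  pids <- cohort$participants$participant_id
  kcal <- vapply(pids, function(p) {
    recall_daily_nutrients(entries[[p]])[["calories"]]
  }, numeric(1))
  expect_equal(unname(kcal),
               exp(cohort$participants$latent_log_calories),
               tolerance = 1e-10)
})

test_that("under-reporting depresses reported calories for high-BMI participants", {
  cohort <- generate_cohort(cohort_params(seed = 44))
  entries <- generate_recall(cohort, day_noise_sd = 0,
                             underreport_slope = 0.03)
  p <- cohort$participants
  kcal <- vapply(p$participant_id, function(id) {
    recall_daily_nutrients(entries[[id]])[["calories"]]
  }, numeric(1))
  heavy <- p$bmi > 25
  expect_lt(mean(kcal[heavy]), mean(exp(p$latent_log_calories[heavy])))
  expect_equal(mean(kcal[!heavy]),
               mean(exp(p$latent_log_calories[!heavy])),
               tolerance = 1e-10)
})

test_that("day-to-day noise attenuates the recall elasticity toward zero", {
  betas <- sapply(c(0, 1.2), function(noise) {
    mean(sapply(1:12, function(s) {
      cohort <- generate_cohort(cohort_params(seed = 500 + s))
      entries <- generate_recall(cohort, day_noise_sd = noise,
                                 underreport_slope = 0)
      pids <- cohort$participants$participant_id
      kcal <- vapply(pids, function(p) {
        recall_daily_nutrients(entries[[p]])[["calories"]]
      }, numeric(1))
      measures <- data.frame(participant_id = pids, tool = "recall",
                             calories = kcal)
      bio <- cohort$participants[, c("participant_id", "weight_kg", "bmi",
                                     "waist_in")]
      unname(fit_elasticity(bio, measures, study_covariates(cohort),
                            dependent = "bmi", tool = "recall")$beta)
    }))
  })
  expect_lt(abs(betas[2]), abs(betas[1]) / 2)
})

test_that("screener generation produces valid, convertible responses", {
  cohort <- generate_cohort(cohort_params(n_participants = 25, seed = 9))
  inst <- default_ffq_instrument()
  responses <- generate_ffq(cohort, inst)
  expect_length(responses, 25)
  kcal <- vapply(responses, function(r) {
    ffq_daily_nutrients(r, inst)[["calories"]]
  }, numeric(1))
  expect_true(all(kcal >= 0))
  expect_gt(cor(kcal, exp(cohort$participants$latent_log_calories)), 0)
})

test_that("a simulated study writes its CSV interfaces", {
  study <- simulate_study(cohort_params(n_participants = 15), seed = 77)
  dir <- tempfile("cohort_")
  write_cohort_csvs(study, dir)
  files <- list.files(dir)
  expect_setequal(files, c("baskets.csv", "ffq_responses.csv",
                           "recall_entries.csv", "biometrics.csv",
                           "covariates.csv", "sessions.csv", "exposures.csv",
                           "measures.csv"))
  baskets <- read_baskets(file.path(dir, "baskets.csv"), default_catalog())
  expect_length(baskets, 15)
  unlink(dir, recursive = TRUE)
})
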
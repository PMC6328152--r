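# In-code fixtures shared across the suite; built fresh per run.

# Six-item catalog, one item per category, round numbers for hand arithmetic.
tiny_catalog <- function() {
  df <- data.frame(
    item_id = c("itemA", "itemB", "itemC", "itemD", "itemE", "itemF"),
    name = c("Apples", "Chicken", "Bread", "Chocolate", "Lasagne", "Juice"),
    category = c("fruit_veg", "meat_fish", "bread_grains", "confectionery",
                 "ready_meals", "drinks"),
    price_pence = c(199L, 350L, 100L, 150L, 250L, 120L),
    pack_size_g = c(750, 460, 800, 200, 430, 1000),
    kcal_100g = c(50, 233.2, 220, 480, 150, 45),
    fat_100g = c(0.5, 14, 2, 22, 7, 0.1),
    satfat_100g = c(0.1, 5, 0.4, 9, 2.5, 0),
    carb_100g = c(10, 8, 42, 60, 15, 10),
    sugar_100g = c(8, 1, 2.5, 34, 2.5, 9.5),
    salt_100g = NA_real_,
    protein_100g = c(1.5, 19, 7, 6, 7, 0.5),
    fibre_100g = NA_real_,
    stringsAsFactors = FALSE
  )
  validate_catalog(df)
  structure(df, class = c("food_catalog", "data.frame"), version = "tiny")
}

tiny_instrument <- function() {
  ffq_instrument(data.frame(
    label = c("Cheese and yoghurt", "Fresh fruit", "Beef, lamb or pork"),
    scale_id = c("standard8", "standard8", "meat6"),
    kcal_100g = c(245.5, 70, 140),
    fat_100g = c(18.5, 0.3, 8),
    satfat_100g = c(11.5, 0.1, 3),
    carb_100g = c(5.5, 16, 1),
    sugar_100g = c(5.2, 14, 0.5),
    protein_100g = c(14, 0.8, 20),
    stringsAsFactors = FALSE
  ))
}

# Random feasible-or-not basket over a catalog, for property tests.
random_basket <- function(catalog, pid = "P1", budget = 3000L,
                          max_qty = 4L) {
  b <- new_basket(pid, budget = budget)
  n_lines <- sample.int(nrow(catalog), 1L)
  picks <- sample(catalog$item_id, n_lines)
  for (iid in picks) b <- set_quantity(b, iid, sample.int(max_qty, 1L), catalog)
  b
}

# Minimal regression tables: log(dep) = intercept + beta*log(cal) + noise.
toy_regression_data <- function(n = 120, beta = 0.1, noise_sd = 0,
                                seed = 1, tool = "basket") {
  set.seed(seed)
  log_cal <- rnorm(n, log(2000), 0.3)
  log_bmi <- 1 + beta * log_cal + rnorm(n, 0, noise_sd)
  pid <- sprintf("P%03d", seq_len(n))
  list(
    biometrics = data.frame(participant_id = pid, weight_kg = 70,
                            bmi = exp(log_bmi), waist_in = 34,
                            stringsAsFactors = FALSE),
    measures = data.frame(participant_id = pid, tool = tool,
                          calories = exp(log_cal), stringsAsFactors = FALSE)
  )
}

study_covariates <- function(cohort) {
  cohort$participants[, c("participant_id", "male", "white", "married",
                          "household_gt1", "age", "employment",
                          "income_band", "session_id")]
}
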
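#' Parameters of the synthetic study cohort
#'
#' Defines the generative model for a synthetic laboratory cohort with the
#' statistical structure the evaluation layer assumes: a latent log daily
#' caloric intake drives weight, BMI and waist size through configurable true
#' elasticities; self-reports (recall, screener) observe the latent intake
#' contaminated by BMI-dependent under-reporting and tool noise; baskets are
#' filled under the budget with a calorie-density bias proportional to the
#' latent propensity. Defaults emulate the reference study population: 255
#' adults in 20 sessions of up to 18, a 3000p budget with a 100p margin, mean
#' weight 73.42 kg and mean BMI 25.36, and true elasticities 0.08 (weight),
#' 0.095 (BMI) and 0.05 (waist).
#'
#' @param n_participants cohort size.
#' @param n_sessions,max_session_size session structure; `n_participants`
#'   must fit into `n_sessions * max_session_size`.
#' @param budget,margin basket budget state in pence.
#' @param true_elasticity named vector: true elasticity of each biometric
#'   with respect to latent calories.
#' @param log_calorie_mean,log_calorie_sd latent log daily kcal distribution.
#' @param biometric_target named vector of target population means (kg,
#'   kg/m^2, inches).
#' @param biometric_noise_sd named vector of log-scale residual SDs.
#' @param male_effect,age_effect named vectors of covariate effects on the
#'   log biometrics (age effect per year).
#' @param male_p,white_p,married_p,household_gt1_p,employed_p,unemployed_p
#'   covariate frequencies.
#' @param age_mean,age_sd age distribution (years; truncated at 18).
#' @param income_probs probabilities of the six income bands (top to bottom).
#' @param underreport_slope under-reporting of self-reported log calories per
#'   BMI unit above 25 (hinge form; illustrative magnitude — the phenomenon
#'   is documented in the literature, its size in this population is not).
#' @param day_noise_sd log-scale day-to-day noise of the 24-hour recall.
#' @param ffq_noise_sd log-scale noise of the screener report.
#' @param basket_bias strength of the calorie-density preference in basket
#'   filling, per SD of latent log calories.
#' @param seed root seed; every random stream is derived from it.
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(n_participants = 255L, n_sessions = 20L,
                          max_session_size = 18L,
                          budget = 3000L, margin = 100L,
                          true_elasticity = c(weight = 0.08, bmi = 0.095,
                                              waist = 0.05),
                          log_calorie_mean = log(2000),
                          log_calorie_sd = 0.29,
                          biometric_target = c(weight = 73.42, bmi = 25.36,
                                               waist = 34),
                          biometric_noise_sd = c(weight = 0.199, bmi = 0.195,
                                                 waist = 0.103),
                          male_effect = c(weight = 0.17, bmi = 0,
                                          waist = 0.10),
                          age_effect = c(weight = 0.002, bmi = 0.0066,
                                         waist = 0.002),
                          male_p = 0.38, white_p = 0.88, married_p = 0.18,
                          household_gt1_p = 0.62,
                          age_mean = 36.91, age_sd = 11.43,
                          employed_p = 0.58, unemployed_p = 0.09,
                          income_probs = c(0.07, 0.30, 0.22, 0.21, 0.13, 0.07),
                          underreport_slope = 0.02,
                          day_noise_sd = 0.5, ffq_noise_sd = 0.4,
                          basket_bias = 2.2,
                          seed = 1L) {
  p <- as.list(environment())
  deps <- c("weight", "bmi", "waist")
  stopifnot(
    all(deps %in% names(p$true_elasticity)),
    all(deps %in% names(p$biometric_target)),
    all(deps %in% names(p$biometric_noise_sd))
  )
  if (p$n_participants > p$n_sessions * p$max_session_size) {
    stop("n_participants (", p$n_participants, ") exceeds session capacity (",
         p$n_sessions * p$max_session_size, ")", call. = FALSE)
  }
  sds <- c(p$log_calorie_sd, p$biometric_noise_sd, p$day_noise_sd,
           p$ffq_noise_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative", call. = FALSE)
  if (p$budget <= 0) stop("budget must be positive", call. = FALSE)
  if (p$underreport_slope < 0) {
    stop("underreport_slope must be non-negative", call. = FALSE)
  }
  if (abs(sum(p$income_probs) - 1) > 1e-8 || length(p$income_probs) != 6L) {
    stop("income_probs must be six probabilities summing to 1", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

income_band_labels <- function() {
  c("above_25k", "20k_25k", "15k_20k", "10k_15k", "5k_10k", "below_5k")
}

#' Generate a synthetic cohort
#'
#' Draws latent log daily calories from the configured normal distribution,
#' covariates from the configured frequencies, and log biometrics as
#' `intercept + elasticity x latent + covariate effects + normal noise`, with
#' intercepts solved in closed form so the population mean of each biometric
#' equals its target. Participants are assigned round-robin to sessions and
#' receive an i.i.d. uniform initial-category exposure. Fully deterministic
#' given the seed.
#'
#' @param params a [cohort_params()].
#' @return A `synthetic_cohort`: list with `participants` (covariates, latent
#'   log calories, biometrics), `sessions` (membership table and
#'   `lab_session` objects), `exposures`, and `params`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_participants = 60, seed = 42))
#' mean(cohort$participants$bmi)
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_participants
  pid <- sprintf("P%03d", seq_len(n))
  session_id <- sprintf("S%02d", rep_len(seq_len(params$n_sessions), n))

  draw <- with_rng(derived_seed(params$seed, "cohort"), {
    latent <- stats::rnorm(n, params$log_calorie_mean, params$log_calorie_sd)
    male <- stats::rbinom(n, 1, params$male_p)
    white <- stats::rbinom(n, 1, params$white_p)
    married <- stats::rbinom(n, 1, params$married_p)
    household_gt1 <- stats::rbinom(n, 1, params$household_gt1_p)
    age <- pmax(18, stats::rnorm(n, params$age_mean, params$age_sd))
    emp <- sample(c("employed", "unemployed", "other"), n, replace = TRUE,
                  prob = c(params$employed_p, params$unemployed_p,
                           1 - params$employed_p - params$unemployed_p))
    income <- sample(income_band_labels(), n, replace = TRUE,
                     prob = params$income_probs)
    noise <- lapply(c(weight = "weight", bmi = "bmi", waist = "waist"),
                    function(d) stats::rnorm(n, 0,
                                             params$biometric_noise_sd[[d]]))
    list(latent = latent, male = male, white = white, married = married,
         household_gt1 = household_gt1, age = age, emp = emp,
         income = income, noise = noise)
  })

  bio <- lapply(c(weight = "weight", bmi = "bmi", waist = "waist"), function(d) {
    beta <- params$true_elasticity[[d]]
    me <- params$male_effect[[d]]
    ae <- params$age_effect[[d]]
    s <- params$biometric_noise_sd[[d]]
    # intercept from the moment generating functions of each additive term,
    # so E[biometric] equals the configured target exactly
    a <- log(params$biometric_target[[d]]) -
      (beta * params$log_calorie_mean + beta^2 * params$log_calorie_sd^2 / 2) -
      log((1 - params$male_p) + params$male_p * exp(me)) -
      (ae * params$age_mean + ae^2 * params$age_sd^2 / 2) -
      s^2 / 2
    exp(a + beta * draw$latent + me * draw$male + ae * draw$age +
          draw$noise[[d]])
  })

  participants <- data.frame(
    participant_id = pid, session_id = session_id,
    male = draw$male, white = draw$white, married = draw$married,
    household_gt1 = draw$household_gt1, age = draw$age,
    employment = draw$emp, income_band = draw$income,
    latent_log_calories = draw$latent,
    weight_kg = bio$weight, bmi = bio$bmi, waist_in = bio$waist,
    stringsAsFactors = FALSE
  )

  sessions <- lapply(split(pid, session_id), function(ids) ids)
  session_objects <- lapply(names(sessions), function(sid) {
    lab_session(sid, sessions[[sid]], seed = params$seed)
  })
  names(session_objects) <- names(sessions)

  exposures <- assign_initial_category(pid, seed = params$seed)

  structure(
    list(participants = participants,
         sessions = list(
           membership = data.frame(session_id = session_id,
                                   participant_id = pid,
                                   stringsAsFactors = FALSE),
           objects = session_objects
         ),
         exposures = exposures, params = params),
    class = "synthetic_cohort"
  )
}

#' Generate budget-respecting baskets for a cohort
#'
#' Fills each participant's basket with a randomized greedy procedure:
#' catalog items are drawn with replacement with sampling weights
#' `exp(bias_i x z_j)`, where `z_j` is the standardized log per-pack calorie
#' content and `bias_i = basket_bias x` the participant's standardized latent
#' log calories, items are kept while they fit the budget, and the residual
#' budget is then topped up with the cheapest affordable items. Every basket
#' is feasible (cost at or below budget) by construction, and basket calories
#' correlate positively with latent intake across the cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param catalog a `food_catalog` (default the packaged fixture).
#' @return Named list of open `food_basket`s, one per participant.
#' @export
generate_baskets <- function(cohort, catalog = default_catalog()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  params <- cohort$params
  if (nrow(catalog) == 0L || min(catalog$price_pence) > params$budget) {
    stop("no catalog item is affordable within the budget of ",
         params$budget, "p", call. = FALSE)
  }
  pack_kcal <- catalog$kcal_100g * catalog$pack_size_g / 100
  z <- as.numeric(scale(log(pmax(pack_kcal, 1e-6))))
  prices <- catalog$price_pence
  cheapest <- min(prices)
  latent <- cohort$participants$latent_log_calories
  bias <- params$basket_bias *
    (latent - params$log_calorie_mean) / params$log_calorie_sd

  baskets <- lapply(seq_len(nrow(cohort$participants)), function(i) {
    pid <- cohort$participants$participant_id[i]
    with_rng(derived_seed(params$seed, paste0("basket:", pid)), {
      w <- exp(bias[i] * z)
      draws <- sample.int(nrow(catalog), 90L, replace = TRUE, prob = w)
      keep <- draws[cumsum(prices[draws]) <= params$budget]
      spend <- sum(prices[keep])
      # top up the residual budget with the cheapest affordable items
      while (params$budget - spend >= cheapest) {
        affordable <- which(prices <= params$budget - spend)
        pick <- affordable[which.min(prices[affordable])]
        keep <- c(keep, pick)
        spend <- spend + prices[pick]
      }
      counts <- table(keep)
      b <- new_basket(pid, budget = params$budget, margin = params$margin)
      lines <- data.frame(
        item_id = catalog$item_id[as.integer(names(counts))],
        quantity = as.integer(counts), stringsAsFactors = FALSE
      )
      b$lines <- lines
      b
    })
  })
  stats::setNames(baskets, cohort$participants$participant_id)
}

reported_log_calories <- function(cohort, noise_sd, stream) {
  params <- cohort$params
  p <- cohort$participants
  with_rng(derived_seed(params$seed, stream), {
    p$latent_log_calories -
      params$underreport_slope * pmax(0, p$bmi - 25) +
      stats::rnorm(nrow(p), 0, noise_sd)
  })
}

# generic foods used to realize recall entry lists; per-100g values
recall_food_table <- function() {
  data.frame(
    food = c("porridge with milk", "cheese sandwich", "cooked dinner plate",
             "chocolate snack bar"),
    share = c(0.25, 0.30, 0.30, 0.15),
    kcal_100g = c(110, 250, 160, 480),
    fat_100g = c(4.5, 9, 6, 25),
    satfat_100g = c(2.5, 5, 2, 14),
    carb_100g = c(13, 30, 18, 55),
    sugar_100g = c(6, 4, 4, 48),
    salt_100g = NA_real_, protein_100g = c(4.8, 11, 8, 6),
    fibre_100g = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Generate 24-hour recall records for a cohort
#'
#' Reported log calories equal the latent value minus the under-reporting
#' hinge (`underreport_slope x max(0, BMI - 25)`) plus day-to-day normal
#' noise; each participant's report is realized as a one-day list of four
#' generic food entries whose portions are solved so the aggregate calories
#' match the reported total exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param day_noise_sd,underreport_slope override the cohort parameters
#'   (e.g. zero for a contamination-free regime).
#' @return Named list of per-participant entry data.frames for
#'   [recall_daily_nutrients()].
#' @export
generate_recall <- function(cohort,
                            day_noise_sd = cohort$params$day_noise_sd,
                            underreport_slope = cohort$params$underreport_slope) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  params <- cohort$params
  params$day_noise_sd <- day_noise_sd
  params$underreport_slope <- underreport_slope
  cohort$params <- params
  kcal <- exp(reported_log_calories(cohort, day_noise_sd, "recall"))
  foods <- recall_food_table()
  entries <- lapply(seq_along(kcal), function(i) {
    df <- foods
    df$portion_g <- df$share * kcal[i] / (df$kcal_100g / 100)
    cbind(data.frame(participant_id = cohort$participants$participant_id[i],
                     stringsAsFactors = FALSE),
          df[, c("food", "portion_g", "kcal_100g", "fat_100g", "satfat_100g",
                 "carb_100g", "sugar_100g", "salt_100g", "protein_100g",
                 "fibre_100g")])
  })
  stats::setNames(entries, cohort$participants$participant_id)
}

# plausible long-run consumption shares over the 23 screener categories;
# names must match the packaged instrument
default_ffq_shares <- function(instrument) {
  labels <- instrument$categories$label
  w <- stats::setNames(rep(1, length(labels)), labels)
  heavier <- c("Bread and rolls", "Rice, pasta and grains",
               "Cheese and yoghurt", "Milk",
               "Beef, lamb or pork", "Chicken or turkey")
  lighter <- c("Green leafy salad", "Fizzy soft drinks", "Fruit juice",
               "Ice cream and desserts")
  w[intersect(heavier, labels)] <- 2
  w[intersect(lighter, labels)] <- 0.5
  w / sum(w)
}

#' Generate screener responses for a cohort
#'
#' Reported log calories follow the same contamination model as the recall
#' (with the screener's own noise SD); the reported total is spread over the
#' instrument's categories according to long-run consumption shares, converted
#' to ideal occasions/day per category, and each ideal frequency is then
#' discretized to the nearest option on that category's scale (ties resolve
#' downward). The resulting answers feed [ffq_daily_nutrients()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param instrument an [ffq_instrument()] (default the packaged screener).
#' @param ffq_noise_sd,underreport_slope override the cohort parameters.
#' @return Named list of per-participant response data.frames.
#' @export
generate_ffq <- function(cohort, instrument = default_ffq_instrument(),
                         ffq_noise_sd = cohort$params$ffq_noise_sd,
                         underreport_slope = cohort$params$underreport_slope) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  params <- cohort$params
  params$ffq_noise_sd <- ffq_noise_sd
  params$underreport_slope <- underreport_slope
  cohort$params <- params
  kcal <- exp(reported_log_calories(cohort, ffq_noise_sd, "ffq"))
  shares <- default_ffq_shares(instrument)
  cats <- instrument$categories
  scale_weights <- lapply(cats$scale_id,
                          function(s) instrument$scales[[s]]$weights)
  responses <- lapply(seq_along(kcal), function(i) {
    ideal <- kcal[i] * shares[cats$label] / cats$kcal_100g
    opt <- vapply(seq_len(nrow(cats)), function(k) {
      w <- scale_weights[[k]]
      names(w)[which.min(abs(w - ideal[k]))]
    }, character(1))
    data.frame(category_label = cats$label, option_label = opt,
               stringsAsFactors = FALSE)
  })
  stats::setNames(responses, cohort$participants$participant_id)
}

#' Assemble the per-participant measurement table
#'
#' Evaluates each instrument on its generated records: basket nutrient totals
#' per participant, recall daily totals, and the screener's converted daily
#' intake, stacked in the long layout the evaluation functions consume.
#'
#' @param cohort a `synthetic_cohort`.
#' @param baskets named list from [generate_baskets()].
#' @param recall_entries named list from [generate_recall()].
#' @param ffq_responses named list from [generate_ffq()].
#' @param catalog,instrument the catalog and instrument the records refer to.
#' @return Long data.frame: `participant_id, tool` plus one column per
#'   nutrient.
#' @export
measurement_records <- function(cohort, baskets, recall_entries,
                                ffq_responses, catalog = default_catalog(),
                                instrument = default_ffq_instrument()) {
  pids <- cohort$participants$participant_id
  one_tool <- function(tool, profiles) {
    cbind(data.frame(participant_id = pids, tool = tool,
                     stringsAsFactors = FALSE),
          as.data.frame(do.call(rbind, lapply(profiles, unclass))))
  }
  basket_profiles <- lapply(pids, function(p) {
    nutrient_totals(baskets[[p]], catalog)
  })
  recall_profiles <- lapply(pids, function(p) {
    recall_daily_nutrients(recall_entries[[p]])
  })
  ffq_profiles <- lapply(pids, function(p) {
    ffq_daily_nutrients(ffq_responses[[p]], instrument)
  })
  out <- rbind(one_tool("basket", basket_profiles),
               one_tool("recall", recall_profiles),
               one_tool("ffq", ffq_profiles))
  rownames(out) <- NULL
  out
}

#' Simulate a complete study
#'
#' One-call wrapper: generates the cohort, baskets, recall and screener
#' records, evaluates all three instruments, and returns the tables the
#' evaluation layer consumes. Byte-identical given the same parameters and
#' seed.
#'
#' @param params a [cohort_params()].
#' @param catalog,instrument the catalog and screener instrument to use.
#' @param seed optional override of `params$seed`.
#' @return A list with `cohort`, `baskets`, `recall_entries`,
#'   `ffq_responses`, `measures`, `biometrics`, `covariates`, `exposures`
#'   and `sessions`.
#' @export
#' @examples
#' study <- simulate_study(cohort_params(n_participants = 80), seed = 7)
#' head(study$measures)
simulate_study <- function(params = cohort_params(),
                           catalog = default_catalog(),
                           instrument = default_ffq_instrument(),
                           seed = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  cohort <- generate_cohort(params)
  baskets <- generate_baskets(cohort, catalog)
  recall_entries <- generate_recall(cohort)
  ffq_responses <- generate_ffq(cohort, instrument)
  measures <- measurement_records(cohort, baskets, recall_entries,
                                  ffq_responses, catalog, instrument)
  p <- cohort$participants
  list(
    cohort = cohort, baskets = baskets, recall_entries = recall_entries,
    ffq_responses = ffq_responses, measures = measures,
    biometrics = p[, c("participant_id", "weight_kg", "bmi", "waist_in")],
    covariates = p[, c("participant_id", "male", "white", "married",
                       "household_gt1", "age", "employment", "income_band",
                       "session_id")],
    exposures = cohort$exposures,
    sessions = cohort$sessions
  )
}

#' Write a simulated study to CSV files
#'
#' Emits the module-level CSV interfaces (baskets, screener responses, recall
#' entries, biometrics, covariates, session membership, exposures, evaluated
#' measures) into a directory, ready for re-analysis or the command-line
#' wrapper.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csvs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  basket_lines <- do.call(rbind, lapply(study$baskets, function(b) {
    if (nrow(b$lines) == 0L) return(NULL)
    cbind(data.frame(participant_id = b$participant_id,
                     stringsAsFactors = FALSE), b$lines)
  }))
  utils::write.csv(basket_lines, file.path(dir, "baskets.csv"),
                   row.names = FALSE)
  ffq <- do.call(rbind, lapply(names(study$ffq_responses), function(p) {
    cbind(data.frame(participant_id = p, stringsAsFactors = FALSE),
          study$ffq_responses[[p]])
  }))
  utils::write.csv(ffq, file.path(dir, "ffq_responses.csv"), row.names = FALSE)
  recall <- do.call(rbind, study$recall_entries)
  utils::write.csv(recall, file.path(dir, "recall_entries.csv"),
                   row.names = FALSE)
  utils::write.csv(study$biometrics, file.path(dir, "biometrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$sessions$membership, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$exposures, file.path(dir, "exposures.csv"),
                   row.names = FALSE)
  utils::write.csv(study$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants in %d sessions (seed %d)\n",
              nrow(x$participants), length(x$sessions$objects),
              x$params$seed))
  invisible(x)
}
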
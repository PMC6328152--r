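#' Distribution of initial category exposure
#'
#' Summarizes the share of participants first shown each of the six categories
#' and tests uniformity (equal 1/6 shares) with a chi-square goodness-of-fit
#' test.
#'
#' @param assignments data.frame `participant_id, front_category` as returned
#'   by [assign_initial_category()].
#' @return A list with `proportions` (named six-vector summing to 1), `counts`,
#'   `chi_square`, `df`, `p_value` and `n`.
#' @export
exposure_distribution <- function(assignments) {
  stopifnot("front_category" %in% names(assignments))
  if (nrow(assignments) == 0L) {
    stop("at least one assignment is required", call. = FALSE)
  }
  counts <- table(factor(assignments$front_category,
                         levels = food_categories()))
  test <- suppressWarnings(
    stats::chisq.test(as.numeric(counts), p = rep(1 / 6, 6))
  )
  list(proportions = stats::setNames(as.numeric(counts) / sum(counts),
                                     food_categories()),
       counts = stats::setNames(as.integer(counts), food_categories()),
       chi_square = unname(test$statistic), df = unname(test$parameter),
       p_value = test$p.value, n = nrow(assignments))
}

#' Build the per-participant category outcome table
#'
#' @param baskets named list of `food_basket`s (names = participant ids).
#' @param catalog the `food_catalog`.
#' @param outcome `"spend"` (pence) or `"count"` (items).
#' @return Wide data.frame: `participant_id` plus one column per category.
#' @export
category_outcome_table <- function(baskets, catalog,
                                   outcome = c("spend", "count")) {
  outcome <- match.arg(outcome)
  fun <- if (outcome == "spend") spend_by_category else items_by_category
  rows <- lapply(names(baskets), function(pid) {
    v <- fun(baskets[[pid]], catalog)
    cbind(data.frame(participant_id = pid, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity of choices to initial category exposure
#'
#' For each of the six dependent categories, regresses the participant-level
#' outcome for that category (expenditure or item count) on five exposure
#' dummies — one per *other* category, with the dependent category itself as
#' the omitted baseline — plus control covariates, with robust standard
#' errors. Under this parameterization, a priming effect of seeing a category
#' first shows up as negative coefficients on the other categories' dummies in
#' that category's regression. Six regressions are fitted per outcome, each
#' with exactly five exposure dummies.
#'
#' @param outcomes wide data.frame from [category_outcome_table()]:
#'   `participant_id` plus one column per category.
#' @param exposures data.frame `participant_id, front_category`; all six
#'   categories must occur at least once.
#' @param covariates optional covariate data.frame as in [fit_elasticity()].
#' @param hc_type sandwich estimator flavor (default `"HC1"`).
#' @return A data.frame of class `exposure_sensitivity`: one row per
#'   (dependent category, exposure dummy) with `estimate`, `robust_se`,
#'   `p_value`, `stars`, `n`; 6 x 5 coefficient rows in total.
#' @export
exposure_sensitivity <- function(outcomes, exposures, covariates = NULL,
                                 hc_type = "HC1") {
  cats <- food_categories()
  stopifnot(all(c("participant_id", cats) %in% names(outcomes)),
            all(c("participant_id", "front_category") %in% names(exposures)))
  seen <- unique(exposures$front_category)
  absent <- setdiff(cats, seen)
  if (length(absent) > 0) {
    stop("exposure category(ies) absent from the data: ",
         paste(absent, collapse = ", "),
         "; the exposure design is deficient", call. = FALSE)
  }
  missing_exp <- setdiff(outcomes$participant_id, exposures$participant_id)
  if (length(missing_exp) > 0) {
    stop("no exposure assignment for participant(s): ",
         paste(utils::head(missing_exp, 5), collapse = ", "), call. = FALSE)
  }
  df <- merge(outcomes, exposures, by = "participant_id")
  covariate_names <- character(0)
  if (!is.null(covariates)) {
    covariate_names <- setdiff(names(covariates), "participant_id")
    cov_df <- covariates
    if ("session_id" %in% covariate_names) {
      cov_df$session_id <- factor(cov_df$session_id)
    }
    df <- merge(df, cov_df, by = "participant_id")
  }
  rows <- lapply(cats, function(dep_cat) {
    other <- setdiff(cats, dep_cat) # the omitted baseline is dep_cat itself
    dummy_cols <- paste0("front_", other)
    for (k in seq_along(other)) {
      df[[dummy_cols[k]]] <- as.integer(df$front_category == other[k])
    }
    rhs <- c(dummy_cols, covariate_names)
    form <- stats::as.formula(paste("`", dep_cat, "` ~ ",
                                    paste(rhs, collapse = " + "), sep = ""))
    fit <- stats::lm(form, data = df)
    check_full_rank(fit)
    ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = hc_type))
    stopifnot(length(dummy_cols) == 5L)
    data.frame(
      dependent_category = dep_cat, front_category = other,
      estimate = unname(ct[dummy_cols, "Estimate"]),
      robust_se = unname(ct[dummy_cols, "Std. Error"]),
      p_value = unname(ct[dummy_cols, "Pr(>|t|)"]),
      stars = p_stars(unname(ct[dummy_cols, "Pr(>|t|)"])),
      n = stats::nobs(fit), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exposure_sensitivity", "data.frame")
  out
}
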
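biometric_column <- function(dependent) {
  switch(dependent,
         weight = "weight_kg", bmi = "bmi", waist = "waist_in",
         stop("dependent must be one of weight, bmi, waist", call. = FALSE))
}

# Assemble the regression frame shared by the mean, quantile and subgroup
# fits: log biometric outcome, log calories per requested tool, covariates
# (session_id expanded to fixed-effect dummies by the model formula).
build_elasticity_frame <- function(biometrics, measures, covariates = NULL,
                                   dependent = "bmi", tools = "basket") {
  stopifnot(all(c("participant_id") %in% names(biometrics)))
  dep_col <- biometric_column(dependent)
  if (!dep_col %in% names(biometrics)) {
    stop("biometrics has no column '", dep_col, "'", call. = FALSE)
  }
  bad_bio <- biometrics$participant_id[
    is.na(biometrics[[dep_col]]) | biometrics[[dep_col]] <= 0]
  if (length(bad_bio) > 0) {
    stop("non-positive ", dependent, " for participant(s): ",
         paste(bad_bio, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(participant_id = as.character(biometrics$participant_id),
                   log_dep = log(biometrics[[dep_col]]),
                   stringsAsFactors = FALSE)
  for (tool in tools) {
    sub <- measures[measures$tool == tool, c("participant_id", "calories")]
    if (nrow(sub) == 0L) {
      stop("no measurements for tool '", tool, "'", call. = FALSE)
    }
    nonpos <- sub$participant_id[is.na(sub$calories) | sub$calories <= 0]
    if (length(nonpos) > 0) {
      # log scale requires positive calories; drop rather than fail the fit
      warning(sprintf("excluding %d participant(s) with non-positive %s calories: %s",
                      length(nonpos), tool,
                      paste(utils::head(nonpos, 5), collapse = ", ")),
              call. = FALSE)
      sub <- sub[!sub$participant_id %in% nonpos, , drop = FALSE]
    }
    col <- paste0("log_cal_", tool)
    sub[[col]] <- log(sub$calories)
    df <- merge(df, sub[, c("participant_id", col)], by = "participant_id")
  }
  covariate_names <- character(0)
  if (!is.null(covariates)) {
    stopifnot("participant_id" %in% names(covariates))
    covariate_names <- setdiff(names(covariates), "participant_id")
    na_cols <- covariate_names[vapply(covariates[covariate_names],
                                      function(v) anyNA(v), logical(1))]
    if (length(na_cols) > 0) {
      stop("covariate column(s) contain missing values: ",
           paste(na_cols, collapse = ", "), call. = FALSE)
    }
    cov_df <- covariates
    cov_df$participant_id <- as.character(cov_df$participant_id)
    if ("session_id" %in% covariate_names) {
      cov_df$session_id <- factor(cov_df$session_id)
    }
    df <- merge(df, cov_df, by = "participant_id")
  }
  attr(df, "covariate_names") <- covariate_names
  attr(df, "tools") <- tools
  df
}

check_full_rank <- function(fit) {
  dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(dropped) > 0) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' Calorie-anthropometry elasticity regression
#'
#' Fits, by OLS, the log of a biometric indicator (weight, BMI or waist size)
#' on the log of the calorie measurement from one dietary assessment tool plus
#' control covariates (optionally including session fixed effects via a
#' `session_id` covariate column), with heteroskedasticity-consistent standard
#' errors. Both sides being in (natural) logs, the calorie coefficient is an
#' elasticity: the percent change in the biometric per 1% change in measured
#' calories. Significance stars mark the 10/5/1% two-sided levels.
#'
#' Passing several tools at once fits the robustness variant with all calorie
#' measures entered in one regression.
#'
#' @param biometrics data.frame `participant_id, weight_kg, bmi, waist_in`
#'   (all strictly positive).
#' @param measures long data.frame `participant_id, tool, calories`.
#'   Participants with non-positive calories are excluded with a warning.
#' @param covariates optional data.frame keyed by `participant_id`; a
#'   `session_id` column is treated as a fixed-effects factor, all other
#'   columns enter the regression as given. No missing values allowed.
#' @param dependent `"weight"`, `"bmi"` or `"waist"`.
#' @param tool tool name(s): subset of `"basket"`, `"recall"`, `"ffq"`.
#' @param hc_type sandwich estimator flavor (default `"HC1"`).
#' @return An `elasticity_fit`: list with `beta`, `robust_se`, `p_value`,
#'   `stars` (named by tool), `r_squared`, `n`, `dependent`, `tool`, the
#'   underlying `lm` `fit` and robust `vcov`.
#' @export
#' @examples
#' study <- simulate_study(cohort_params(n_participants = 120), seed = 1)
#' fit_elasticity(study$biometrics, study$measures, study$covariates,
#'                dependent = "bmi", tool = "basket")
fit_elasticity <- function(biometrics, measures, covariates = NULL,
                           dependent = c("bmi", "weight", "waist"),
                           tool = "basket", hc_type = "HC1") {
  dependent <- match.arg(dependent)
  df <- build_elasticity_frame(biometrics, measures, covariates,
                               dependent, tools = tool)
  cal_cols <- paste0("log_cal_", tool)
  for (col in cal_cols) {
    if (stats::sd(df[[col]]) == 0) {
      stop("design matrix is rank deficient; collinear column(s): ", col,
           call. = FALSE)
    }
  }
  rhs <- c(cal_cols, attr(df, "covariate_names"))
  form <- stats::as.formula(paste("log_dep ~", paste(rhs, collapse = " + ")))
  if (nrow(df) <= length(rhs) + 1L) {
    stop("too few observations (", nrow(df), ") for ", length(rhs) + 1L,
         " regressors", call. = FALSE)
  }
  fit <- stats::lm(form, data = df)
  check_full_rank(fit)
  vc <- sandwich::vcovHC(fit, type = hc_type)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  beta <- stats::setNames(ct[cal_cols, "Estimate"], tool)
  se <- stats::setNames(ct[cal_cols, "Std. Error"], tool)
  p <- stats::setNames(ct[cal_cols, "Pr(>|t|)"], tool)
  structure(
    list(beta = beta, robust_se = se, p_value = p, stars = p_stars(p),
         r_squared = summary(fit)$r.squared, n = stats::nobs(fit),
         dependent = dependent, tool = tool, hc_type = hc_type,
         fit = fit, vcov = vc),
    class = "elasticity_fit"
  )
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat(sprintf("<elasticity_fit> log(%s) ~ log(calories[%s]) + controls\n",
              x$dependent, paste(x$tool, collapse = ", ")))
  for (i in seq_along(x$beta)) {
    cat(sprintf("  %-8s beta = %.4f%s (robust SE %.4f)\n", names(x$beta)[i],
                x$beta[i], x$stars[i], x$robust_se[i]))
  }
  cat(sprintf("  n = %d, R-squared = %.3f  [* 10%%, ** 5%%, *** 1%%]\n",
              x$n, x$r_squared))
  invisible(x)
}
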
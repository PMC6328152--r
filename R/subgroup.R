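#' Subgroup elasticities with a between-group difference test
#'
#' Fits [fit_elasticity()] independently within the two levels of a binary
#' split (e.g. gender, or married/household-larger-than-one vs the rest), and
#' tests whether the calorie elasticity differs between the groups via the
#' interaction term of a pooled regression (log calories interacted with the
#' group indicator, with the group main effect and all other covariates
#' retained), using heteroskedasticity-consistent standard errors.
#'
#' @inheritParams fit_elasticity
#' @param split name of a binary column of `covariates` defining the two
#'   subgroups (coerced with `as.logical`/0-1 semantics).
#' @return A list of class `subgroup_elasticity`: per-group `elasticity_fit`s
#'   under `fits` (named by group label), and `difference` with the pooled
#'   interaction `estimate`, `robust_se`, `p_value` and `stars`.
#' @export
subgroup_elasticity <- function(biometrics, measures, covariates,
                                dependent = c("bmi", "weight", "waist"),
                                tool = "basket", split = "male",
                                hc_type = "HC1") {
  dependent <- match.arg(dependent)
  stopifnot(length(tool) == 1L)
  if (!split %in% names(covariates)) {
    stop("covariates has no column '", split, "'", call. = FALSE)
  }
  g <- covariates[[split]]
  if (anyNA(g) || !all(g %in% c(0, 1, TRUE, FALSE))) {
    stop("split column '", split, "' must be binary with no missing values",
         call. = FALSE)
  }
  g <- as.integer(as.logical(g))
  other <- covariates[, setdiff(names(covariates), split), drop = FALSE]
  groups <- list(`0` = covariates$participant_id[g == 0],
                 `1` = covariates$participant_id[g == 1])
  fits <- lapply(names(groups), function(lev) {
    ids <- groups[[lev]]
    if (length(ids) == 0L) {
      stop("subgroup ", split, " = ", lev, " is empty", call. = FALSE)
    }
    keep_cov <- other[other$participant_id %in% ids, , drop = FALSE]
    keep_bio <- biometrics[biometrics$participant_id %in% ids, , drop = FALSE]
    keep_mea <- measures[measures$participant_id %in% ids, , drop = FALSE]
    n_reg <- 2L + length(setdiff(names(keep_cov), "participant_id"))
    if (length(ids) <= n_reg) {
      stop("subgroup ", split, " = ", lev, " has too few participants (",
           length(ids), ") for the regression", call. = FALSE)
    }
    fit_elasticity(keep_bio, keep_mea, keep_cov, dependent = dependent,
                   tool = tool, hc_type = hc_type)
  })
  names(fits) <- paste0(split, " = ", names(groups))

  # pooled model with interaction for the difference test
  df <- build_elasticity_frame(biometrics, measures, covariates,
                               dependent, tools = tool)
  cal_col <- paste0("log_cal_", tool)
  df$.group <- as.integer(as.logical(df[[split]]))
  df$.interaction <- df[[cal_col]] * df$.group
  rhs <- c(cal_col, ".group", ".interaction",
           setdiff(attr(df, "covariate_names"), split))
  form <- stats::as.formula(paste("log_dep ~", paste(rhs, collapse = " + ")))
  pooled <- stats::lm(form, data = df)
  check_full_rank(pooled)
  ct <- lmtest::coeftest(pooled, vcov. = sandwich::vcovHC(pooled, type = hc_type))
  est <- unname(ct[".interaction", "Estimate"])
  se <- unname(ct[".interaction", "Std. Error"])
  p <- unname(ct[".interaction", "Pr(>|t|)"])
  structure(
    list(fits = fits,
         difference = list(estimate = est, robust_se = se, p_value = p,
                           stars = p_stars(p)),
         split = split, dependent = dependent, tool = tool),
    class = "subgroup_elasticity"
  )
}

#' @export
print.subgroup_elasticity <- function(x, ...) {
  cat(sprintf("<subgroup_elasticity> log(%s) ~ log(calories[%s]), split by %s\n",
              x$dependent, x$tool, x$split))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-22s beta = %.4f%s (robust SE %.4f), n = %d\n", nm,
                f$beta, f$stars, f$robust_se, f$n))
  }
  d <- x$difference
  cat(sprintf("  difference (interaction): %.4f%s (robust SE %.4f, p = %.3f)\n",
              d$estimate, d$stars, d$robust_se, d$p_value))
  invisible(x)
}
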
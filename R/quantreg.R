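# Quantile regression by direct minimization of the check-function loss.
#
# The estimator minimizes sum_i rho_tau(y_i - x_i'b) with
# rho_tau(r) = r * (tau - 1{r < 0}). The objective is piecewise linear; we
# minimize a smoothed version rho_tau_eps(r) = tau*r + eps*log(1 + exp(-r/eps))
# (which converges uniformly to rho_tau as eps -> 0) by BFGS with an analytic
# gradient, annealing eps downward, warm-started at the OLS solution with its
# intercept shifted to the tau-th residual quantile. The final coefficients are
# kept only if they improve the exact (non-smoothed) loss over the warm start,
# so the fitted line is never worse than OLS under absolute-deviation loss.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

smooth_check <- function(r, tau, eps) {
  # numerically stable: eps*log(1+exp(-r/eps)) = eps*log1p(exp(-|r|/eps)) + max(-r, 0)
  sum(tau * r + eps * log1p(exp(-abs(r) / eps)) + pmax(-r, 0))
}

rq_fit <- function(X, y, tau, max_restarts = 2L) {
  stopifnot(tau > 0, tau < 1, nrow(X) == length(y))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "),
         call. = FALSE)
  }
  b0 <- qr.coef(qrX, y)
  res0 <- y - X %*% b0
  if ("(Intercept)" %in% colnames(X)) {
    b0["(Intercept)"] <- b0["(Intercept)"] +
      stats::quantile(res0, probs = tau, names = FALSE)
  }
  scale <- stats::mad(res0, constant = 1)
  if (!is.finite(scale) || scale <= 0) scale <- max(stats::sd(res0), 1e-8)
  b <- b0
  for (eps in scale * c(0.5, 0.1, 0.02, 0.004, 5e-4)) {
    opt <- stats::optim(
      b,
      fn = function(beta) smooth_check(y - drop(X %*% beta), tau, eps),
      gr = function(beta) {
        r <- y - drop(X %*% beta)
        psi <- tau - 1 / (1 + exp(pmin(r / eps, 700)))
        -drop(crossprod(X, psi))
      },
      method = "BFGS",
      control = list(maxit = 400, reltol = 1e-12)
    )
    b <- opt$par
  }
  loss_fit <- check_loss(y - drop(X %*% b), tau)
  loss_start <- check_loss(y - drop(X %*% b0), tau)
  if (loss_start < loss_fit) {
    b <- b0
    loss_fit <- loss_start
  }
  list(coefficients = stats::setNames(drop(b), colnames(X)),
       loss = loss_fit, tau = tau)
}

#' Quantile-regression elasticities
#'
#' Estimates the conditional-quantile analogue of [fit_elasticity()] at one or
#' more quantiles of the biometric distribution: the check-function loss is
#' minimized for log(biometric) on log(calories) plus covariates, so the
#' calorie coefficient at quantile `q` describes the elasticity among
#' participants at that point of the outcome distribution (e.g. q90 for the
#' heaviest decile). Standard errors come from a nonparametric bootstrap
#' (resampling participants) with a configurable replicate count and seed.
#'
#' @inheritParams fit_elasticity
#' @param q quantiles to fit (default the deciles/quartiles/median grid
#'   `0.10, 0.25, 0.50, 0.75, 0.90`).
#' @param boot_reps bootstrap replicates for the standard errors.
#' @param seed integer seed for the bootstrap resampling.
#' @return A data.frame of class `quantile_elasticity` with one row per
#'   quantile: `q, beta, boot_se, p_value, stars, n, dependent, tool`.
#' @export
quantile_elasticity <- function(biometrics, measures, covariates = NULL,
                                dependent = c("bmi", "weight", "waist"),
                                tool = "basket",
                                q = c(0.10, 0.25, 0.50, 0.75, 0.90),
                                boot_reps = 100L, seed = 1L) {
  dependent <- match.arg(dependent)
  stopifnot(length(tool) == 1L, all(q > 0 & q < 1))
  df <- build_elasticity_frame(biometrics, measures, covariates,
                               dependent, tools = tool)
  cal_col <- paste0("log_cal_", tool)
  rhs <- c(cal_col, attr(df, "covariate_names"))
  form <- stats::as.formula(paste("log_dep ~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(form, data = df)
  y <- df$log_dep
  if (nrow(X) <= ncol(X)) {
    stop("too few observations (", nrow(X), ") for ", ncol(X), " regressors",
         call. = FALSE)
  }
  rows <- lapply(q, function(tau) {
    fit <- rq_fit(X, y, tau)
    beta <- fit$coefficients[[cal_col]]
    boot <- with_rng(derived_seed(seed, sprintf("rqboot:%s:%s:%.3f",
                                                dependent, tool, tau)), {
      vapply(seq_len(boot_reps), function(b) {
        idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
        bf <- tryCatch(rq_fit(X[idx, , drop = FALSE], y[idx], tau),
                       error = function(e) NULL)
        if (is.null(bf)) NA_real_ else bf$coefficients[[cal_col]]
      }, numeric(1))
    })
    boot <- boot[!is.na(boot)]
    if (length(boot) < boot_reps / 2) {
      stop(sprintf("quantile fit unstable at q = %.2f: too many failed bootstrap replicates",
                   tau), call. = FALSE)
    }
    se <- stats::sd(boot)
    pz <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(q = tau, beta = beta, boot_se = se, p_value = pz,
               stars = p_stars(pz), n = nrow(X), dependent = dependent,
               tool = tool, loss = fit$loss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quantile_elasticity", "data.frame")
  out
}
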
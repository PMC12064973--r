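# Metric core without the user-facing validation/warnings (used by the
# bootstrap, where degenerate resamples legitimately yield NA R^2).
metrics_core <- function(observed, predicted) {
  res <- observed - predicted
  mse <- mean(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  list(mse = mse, rmse = sqrt(mse), r2 = r2, residuals = res)
}

#' Fit-quality metrics for a pair of daily curves
#'
#' Mean square error, root mean square error and goodness of fit between the
#' observed and model-predicted daily adherence proportions. `R^2` is
#' `1 - SS_res / SS_tot` about the observed mean; it is reported unclipped
#' (negative values are meaningful) and is `NA` with a warning when the
#' observed series is constant.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return List with `mse`, `rmse`, `r2` and `residuals`
#'   (observed - predicted, per day).
#' @examples
#' fit_metrics(c(0, 1), c(0.5, 0.5))  # mse 0.25, r2 0
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 days to compute fit metrics", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("curves must be finite", call. = FALSE)
  out <- metrics_core(observed, predicted)
  if (is.na(out$r2))
    warning("observed series is constant: R^2 is undefined and reported as NA",
            call. = FALSE)
  out
}

#' Bootstrap confidence intervals for the fit metrics
#'
#' Percentile bootstrap over participants: each replicate resamples the
#' cohort's participants with replacement, recomputes the observed and
#' predicted group curves under the *fixed* supplied coefficients (no
#' refitting), and recomputes MSE, RMSE and R^2. Degenerate replicates with a
#' constant observed curve yield `NA` R^2 and are dropped from that interval.
#'
#' @param cohort An [adherence_cohort()] with >= 2 participants.
#' @param fp An [free_params()] (typically the fitted coefficients).
#' @param sys An [system_params()].
#' @param decay An [decay_config()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Coverage of the percentile interval (default 0.90).
#' @param seed Integer seed; results are reproducible given it.
#' @param refit If `TRUE`, refit the five coefficients on every replicate
#'   (expensive); by default the coefficients are held fixed.
#' @param control [fit_control()] used only when `refit = TRUE`.
#' @return List with `ci_mse`, `ci_rmse`, `ci_r2` (each `c(lo, hi)`), `level`,
#'   `B` and the full `replicates` data frame.
#' @export
bootstrap_ci <- function(cohort, fp, sys = system_params(),
                         decay = decay_config(), B = 1000, level = 0.90,
                         seed = 1, refit = FALSE, control = fit_control()) {
  stopifnot(inherits(fp, "actr_free"))
  if (B < 2) stop("`B` must be >= 2", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  m <- cohort_matrix(cohort)
  n <- nrow(m)
  if (n < 2L)
    stop("bootstrap resampling is degenerate for a cohort of 1 participant",
         call. = FALSE)
  design <- model_design(cohort, sys, decay)
  P <- prob_matrix(fp_vector(fp), design, sys)
  set.seed(seed)
  reps <- matrix(NA_real_, B, 3L,
                 dimnames = list(NULL, c("mse", "rmse", "r2")))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    obs_b <- colMeans(m[idx, , drop = FALSE])
    pred_b <- if (refit) {
      sub <- adherence_cohort(m[idx, , drop = FALSE],
                              group = attr(cohort, "group"),
                              ids = sprintf("b%d", seq_len(n)))
      refitted <- fit_adherence(sub, sys, decay, control)
      refitted$fitted_curve
    } else {
      colMeans(P[idx, , drop = FALSE])
    }
    met <- metrics_core(obs_b, pred_b)
    reps[b, ] <- c(met$mse, met$rmse, met$r2)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- function(col) unname(stats::quantile(reps[, col], probs, na.rm = TRUE))
  list(ci_mse = ci("mse"), ci_rmse = ci("rmse"), ci_r2 = ci("r2"),
       level = level, B = B, replicates = as.data.frame(reps))
}

#' Ljung-Box test for residual autocorrelation
#'
#' Portmanteau test `Q = n(n+2) * sum_k rho_k^2 / (n - k)` over the first
#' `lags` residual autocorrelations, compared against a chi-square with
#' `lags` degrees of freedom. On a 21-day residual series the default of 20
#' lags spends nearly every degree of freedom, which is statistically
#' degenerate; a warning says so.
#'
#' @param residuals Per-day residual series, length >= `lags + 1`, non-constant.
#' @param lags Number of autocorrelation lags (default 20).
#' @return List with `statistic`, `p_value`, `lags`.
#' @export
ljung_box <- function(residuals, lags = 20) {
  n <- length(residuals)
  lags <- as.integer(lags)
  if (lags < 1L) stop("`lags` must be >= 1", call. = FALSE)
  if (n < lags + 1L)
    stop("series length must be at least lags + 1", call. = FALSE)
  if (stats::var(residuals) == 0)
    stop("residuals have zero variance: autocorrelation is undefined",
         call. = FALSE)
  if (lags >= n - 1L)
    warning("lags is close to the series length; the test is statistically degenerate",
            call. = FALSE)
  bt <- stats::Box.test(residuals, lag = lags, type = "Ljung-Box")
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
       lags = lags)
}

#' Full evaluation report for a fitted model
#'
#' Assembles the point metrics, their bootstrap percentile confidence
#' intervals and the Ljung-Box residual diagnostic into one report, together
#' with the exportable fitted-versus-actual and residual tables.
#'
#' @param fit An [fit_adherence()] result.
#' @param B,level Bootstrap replicates and CI coverage (defaults 1000, 0.90).
#' @param lags Ljung-Box lags (default 20).
#' @param seed Integer seed for the bootstrap.
#' @param refit Refit coefficients per bootstrap replicate (default `FALSE`).
#' @return An object of class `"adherence_eval"`: `mse`, `rmse`, `r2`,
#'   `ci_mse`, `ci_rmse`, `ci_r2`, `lb_stat`, `lb_p`, `residuals`,
#'   `fitted_vs_actual` (day, observed, predicted) and `residual_table`
#'   (day, residual).
#' @export
evaluate_fit <- function(fit, B = 1000, level = 0.90, lags = 20, seed = 1,
                         refit = FALSE) {
  if (!inherits(fit, "adherence_fit"))
    stop("`fit` must be an adherence_fit object", call. = FALSE)
  met <- metrics_core(fit$observed, fit$fitted_curve)
  ci <- bootstrap_ci(fit$cohort, fit$free_params, fit$system, fit$decay,
                     B = B, level = level, seed = seed, refit = refit,
                     control = fit$control)
  lb <- ljung_box(met$residuals, lags = lags)
  days <- seq_along(fit$observed)
  structure(list(
    mse = met$mse, rmse = met$rmse, r2 = met$r2,
    ci_mse = ci$ci_mse, ci_rmse = ci$ci_rmse, ci_r2 = ci$ci_r2,
    lb_stat = lb$statistic, lb_p = lb$p_value, lags = lags,
    level = level, B = B,
    residuals = met$residuals,
    fitted_vs_actual = data.frame(day = days, observed = fit$observed,
                                  predicted = fit$fitted_curve),
    residual_table = data.frame(day = days, residual = met$residuals)),
    class = "adherence_eval")
}

#' @export
print.adherence_eval <- function(x, ...) {
  pct <- round(100 * x$level)
  fmt <- function(v, ci) {
    if (is.na(v)) return(sprintf("NA (%.4f to %.4f)", ci[1], ci[2]))
    sprintf("%.4f (%.4f to %.4f)", v, ci[1], ci[2])
  }
  cat(sprintf("Evaluation (value, %d%% CI over %d bootstrap replicates)\n",
              pct, x$B))
  cat("  MSE  ", fmt(x$mse, x$ci_mse), "\n")
  cat("  RMSE ", fmt(x$rmse, x$ci_rmse), "\n")
  cat("  R^2  ", fmt(x$r2, x$ci_r2), "\n")
  cat(sprintf("  Ljung-Box (%d lags): Q = %.4f, p = %.3g\n",
              x$lags, x$lb_stat, x$lb_p))
  invisible(x)
}
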
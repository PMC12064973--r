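# Precompute the parts of the model that depend only on the observed
# histories and the fixed system parameters: the base-level activation matrix
# B (NA where the history is empty) and the prior-execution count matrix K.
# The five free coefficients then enter the predicted probabilities in closed
# form, which makes the fitting objective cheap. Identical sequences are
# collapsed to one weighted row (`map` recovers the participant order).
model_design <- function(cohort, sys, decay) {
  m <- cohort_matrix(cohort)
  n_days <- ncol(m)
  key <- apply(m, 1L, paste, collapse = "")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  mu <- m[uniq, , drop = FALSE]
  w <- as.vector(tabulate(map, nbins = nrow(mu)))
  n <- nrow(mu)
  B <- matrix(NA_real_, n, n_days)
  K <- matrix(0, n, n_days)
  for (i in seq_len(n)) {
    execd <- which(mu[i, ] == 1L)
    if (length(execd) > 0L) {
      # decays depend only on inter-practice spacing; evaluate once
      d <- practice_decays((n_days + 1L) - execd, decay, sys)
      for (nn in seq_len(n_days)) {
        prior <- execd < nn
        if (any(prior))
          B[i, nn] <- log(sum((nn - execd[prior])^(-d[prior])))
      }
    }
    K[i, ] <- c(0, cumsum(mu[i, ]))[seq_len(n_days)]
  }
  list(B = B, K = K, w = w / sum(w), map = map,
       obs = unname(colMeans(m)), n = nrow(m), n_days = n_days)
}

# Model pieces at a coefficient vector (beta0, beta, Tr, U0, R0) on the
# deduplicated design rows.
prob_pieces <- function(par, design, sys) {
  B0 <- design$B
  empty <- is.na(B0)
  B0[empty] <- 0
  A <- par[1L] + par[2L] * B0
  P_G <- stats::plogis((A - sys$tau) / sys$s)
  Ap <- if (sys$translation == "multiplicative") par[3L] * A else A + par[3L]
  P_S <- stats::plogis((Ap - sys$tau) / sys$s)
  q <- (1 - sys$alpha)^design$K
  U <- par[5L] + (par[4L] - par[5L]) * q
  P_H <- stats::plogis(U / (sqrt(2) * sys$s_u))
  list(A = A, B0 = B0, empty = empty, P_G = P_G, P_S = P_S, q = q, U = U,
       P_H = P_H, P = P_G * P_S + (1 - P_G) * P_H)
}

# N x T matrix of composite success probabilities, one row per participant.
prob_matrix <- function(par, design, sys) {
  prob_pieces(par, design, sys)$P[design$map, , drop = FALSE]
}

design_curve <- function(par, design, sys) {
  as.vector(design$w %*% prob_pieces(par, design, sys)$P)
}

design_objective <- function(par, design, sys) {
  pred <- design_curve(par, design, sys)
  if (any(!is.finite(pred)))
    stop("non-finite model output at parameters (",
         paste(signif(par, 6), collapse = ", "), ")", call. = FALSE)
  mean((design$obs - pred)^2)
}

# Analytic gradient of design_objective by the chain rule through the two
# logistic stages and the utility fixed-point form.
design_gradient <- function(par, design, sys) {
  pc <- prob_pieces(par, design, sys)
  dPG <- pc$P_G * (1 - pc$P_G) / sys$s
  dPS <- pc$P_S * (1 - pc$P_S) / sys$s
  dPH_dU <- pc$P_H * (1 - pc$P_H) / (sqrt(2) * sys$s_u)
  if (sys$translation == "multiplicative") {
    dP_dA <- dPG * (pc$P_S - pc$P_H) + pc$P_G * dPS * par[3L]
    dP_dTr <- pc$P_G * dPS * pc$A
  } else {
    dP_dA <- dPG * (pc$P_S - pc$P_H) + pc$P_G * dPS
    dP_dTr <- pc$P_G * dPS
  }
  dB <- pc$B0
  dB[pc$empty] <- 0 # empty history: A does not depend on beta
  oneG <- 1 - pc$P_G
  grads <- list(
    beta0 = dP_dA,
    beta = dP_dA * dB,
    Tr = dP_dTr,
    U0 = oneG * dPH_dU * pc$q,
    R0 = oneG * dPH_dU * (1 - pc$q))
  pred <- as.vector(design$w %*% pc$P)
  resid <- design$obs - pred
  vapply(grads, function(g) {
    dpred <- as.vector(design$w %*% g)
    mean(-2 * resid * dpred)
  }, numeric(1))
}

#' Group-level fitting objective
#'
#' Mean over days of the squared discrepancy between the observed daily
#' adherence proportion and the mean predicted success probability (each
#' participant's prediction conditioned on their own observed history). All
#' days contribute, including day 1 under the empty-history convention.
#'
#' @param fp An [free_params()].
#' @param cohort An [adherence_cohort()], all-zero participants already
#'   excluded.
#' @param sys An [system_params()].
#' @param decay An [decay_config()].
#' @return Non-negative scalar.
#' @seealso [fit_adherence()]
#' @export
adherence_objective <- function(fp, cohort, sys = system_params(),
                                decay = decay_config()) {
  stopifnot(inherits(fp, "actr_free"))
  design <- model_design(cohort, sys, decay)
  design_objective(fp_vector(fp), design, sys)
}

#' Control settings for multi-start BFGS fitting
#'
#' @param n_starts Number of random initializations (>= 1).
#' @param init_ranges 5 x 2 matrix of sampling intervals for the starts, rows
#'   in the order beta0, beta, Tr, U0, R0. The defaults
#'   (`[-5,5]`, `[-5,5]`, `[0,5]`, `[-5,5]`, `[0,5]`) cover the plausible
#'   coefficient scale; the composite logistic objective is multimodal, hence
#'   the multi-start.
#' @param tol Relative convergence tolerance on the objective.
#' @param max_iter Iteration cap per start.
#' @param seed Integer seed controlling the random starts.
#' @param gradient `"analytic"` (default; exact chain-rule gradient) or
#'   `"numeric"` (central finite differences). The two agree to numerical
#'   precision; the analytic form is simply cheaper.
#' @param grad_step Central-difference step for the numerical gradient.
#' @return An object of class `"fit_control"`.
#' @export
fit_control <- function(n_starts = 20, init_ranges = NULL, tol = 1e-8,
                        max_iter = 500, seed = 1,
                        gradient = c("analytic", "numeric"),
                        grad_step = 1e-6) {
  gradient <- match.arg(gradient)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  if (is.null(init_ranges)) {
    init_ranges <- rbind(beta0 = c(-5, 5), beta = c(-5, 5), Tr = c(0, 5),
                         U0 = c(-5, 5), R0 = c(0, 5))
  }
  init_ranges <- as.matrix(init_ranges)
  if (!identical(dim(init_ranges), c(5L, 2L)) ||
      any(init_ranges[, 2L] < init_ranges[, 1L]))
    stop("`init_ranges` must be a 5 x 2 matrix of lo <= hi intervals",
         call. = FALSE)
  structure(list(n_starts = as.integer(n_starts), init_ranges = init_ranges,
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), gradient = gradient,
                 grad_step = grad_step),
            class = "fit_control")
}

central_grad <- function(par, f, h) {
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par))
    e[j] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}

#' Fit the adherence model to a cohort
#'
#' Estimates the five free coefficients of the goal-pursuit /
#' habit-formation model for one study arm by minimizing the mean squared
#' discrepancy between the observed daily adherence proportion and the mean
#' predicted success probability (see [adherence_objective()]). Optimization
#' is unconstrained BFGS with a central-difference gradient, restarted from
#' `n_starts` random initializations; the lowest-objective solution is
#' returned. The whole procedure is deterministic given the cohort and the
#' control seed.
#'
#' @param cohort An [adherence_cohort()] with at least two participants;
#'   all-zero sequences should have been removed with [exclude_all_zero()]
#'   first (a warning is raised otherwise).
#' @param system An [system_params()].
#' @param decay An [decay_config()].
#' @param control A [fit_control()].
#' @return An object of class `"adherence_fit"` with components
#'   `coefficients` (named vector), `free_params`, `objective` (mean squared
#'   discrepancy at the optimum), `converged`, `n_starts`, `best_start`,
#'   `starts` (per-start diagnostics), `observed` and `fitted_curve` (daily
#'   proportions), plus the inputs needed by the methods. Supports `print()`,
#'   `summary()`, `coef()`, `fitted()`, `residuals()`, `predict()`, `plot()`
#'   and `simulate()`.
#' @examples
#' \donttest{
#' arm <- simulate_group(group_presets()$tailored_feedback, seed = 1)
#' fit <- fit_adherence(arm$cohort, control = fit_control(n_starts = 5))
#' coef(fit)
#' }
#' @export
fit_adherence <- function(cohort, system = system_params(),
                          decay = decay_config(), control = fit_control()) {
  if (!inherits(control, "fit_control"))
    stop("`control` must be created by fit_control()", call. = FALSE)
  m <- cohort_matrix(cohort)
  if (nrow(m) < 2L)
    stop("fitting needs a cohort of at least 2 participants", call. = FALSE)
  if (any(rowSums(m) == 0L))
    warning("cohort contains all-zero sequences; run exclude_all_zero() first",
            call. = FALSE)
  design <- model_design(cohort, system, decay)
  obj <- function(par) design_objective(par, design, system)
  grad <- if (control$gradient == "analytic") {
    function(par) design_gradient(par, design, system)
  } else {
    function(par) central_grad(par, obj, control$grad_step)
  }

  set.seed(control$seed)
  lo <- control$init_ranges[, 1L]
  span <- control$init_ranges[, 2L] - lo
  runs <- vector("list", control$n_starts)
  for (k in seq_len(control$n_starts)) {
    start <- lo + stats::runif(5) * span # drawn sequentially: starts nest in n_starts
    runs[[k]] <- tryCatch(
      c(stats::optim(start, obj, gr = grad, method = "BFGS",
                     control = list(maxit = control$max_iter,
                                    reltol = control$tol))[
        c("par", "value", "convergence")],
        list(start = start, error = NA_character_)),
      error = function(e) list(par = rep(NA_real_, 5), value = Inf,
                               convergence = NA_integer_, start = start,
                               error = conditionMessage(e)))
  }
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) {
    diag <- paste(sprintf("start %d: %s", seq_along(runs),
                          vapply(runs, `[[`, character(1), "error")),
                  collapse = "; ")
    stop("no BFGS start converged; per-start diagnostics: ", diag, call. = FALSE)
  }
  best <- which.min(values)
  par <- runs[[best]]$par
  names(par) <- c("beta0", "beta", "Tr", "U0", "R0")
  starts <- data.frame(
    start = seq_along(runs),
    objective = values,
    convergence = vapply(runs, `[[`, numeric(1), "convergence"),
    error = vapply(runs, `[[`, character(1), "error"))

  structure(list(
    coefficients = par,
    free_params = fp_from_vector(par),
    objective = values[best],
    converged = identical(runs[[best]]$convergence, 0L) ||
      isTRUE(runs[[best]]$convergence == 0),
    n_starts = control$n_starts,
    best_start = best,
    seed = control$seed,
    starts = starts,
    observed = design$obs,
    fitted_curve = colMeans(prob_matrix(par, design, system)),
    cohort = cohort,
    system = system,
    decay = decay,
    control = control,
    call = match.call()),
    class = "adherence_fit")
}

#' @export
print.adherence_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Adherence model fit, group '%s' (%d participants x %d days)\n",
              attr(x$cohort, "group"), nrow(x$cohort), length(x$observed)))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Objective (MSE): %.6g  RMSE: %.4f  [%d starts, best #%d%s]\n",
              x$objective, sqrt(x$objective), x$n_starts, x$best_start,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
coef.adherence_fit <- function(object, ...) object$coefficients

#' @export
fitted.adherence_fit <- function(object, ...) object$fitted_curve

#' @export
residuals.adherence_fit <- function(object, ...) {
  object$observed - object$fitted_curve
}

#' @rdname fit_adherence
#' @param object,x An `adherence_fit` object.
#' @param newdata Optional [adherence_cohort()] to predict for (defaults to
#'   the training cohort).
#' @param type `"curve"` for the daily mean predicted success probability,
#'   `"traces"` for the tidy per-participant-day trace table (one row per
#'   participant and day with all model internals).
#' @param ... Passed on / ignored.
#' @export
predict.adherence_fit <- function(object, newdata = NULL,
                                  type = c("curve", "traces"), ...) {
  type <- match.arg(type)
  cohort <- if (is.null(newdata)) object$cohort else newdata
  if (type == "curve") {
    design <- model_design(cohort, object$system, object$decay)
    return(colMeans(prob_matrix(object$coefficients, design, object$system)))
  }
  m <- cohort_matrix(cohort)
  out <- lapply(seq_len(nrow(m)), function(i) {
    tr <- predict_sequence(m[i, ], object$free_params, object$system,
                           object$decay)
    cbind(participant_id = rownames(m)[i], tr)
  })
  do.call(rbind, out)
}

#' @export
summary.adherence_fit <- function(object, ...) {
  met <- fit_metrics(object$observed, object$fitted_curve)
  structure(list(fit = object, mse = met$mse, rmse = met$rmse, r2 = met$r2),
            class = "summary.adherence_fit")
}

#' @export
print.summary.adherence_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("MSE %.4f  RMSE %.4f  R^2 %s\n", x$mse, x$rmse,
              if (is.na(x$r2)) "NA (constant observed curve)"
              else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' @rdname fit_adherence
#' @export
plot.adherence_fit <- function(x, ...) {
  days <- seq_along(x$observed)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(days, x$observed, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "day", ylab = "adherence proportion",
                 main = attr(x$cohort, "group"), ...)
  graphics::lines(days, x$fitted_curve, col = "red", lwd = 2)
  graphics::legend("bottomleft", legend = c("observed", "fitted"),
                   col = c("black", "red"), lty = 1, pch = c(16, NA), bty = "n")
  graphics::plot(days, residuals(x), pch = 16, xlab = "day",
                 ylab = "residual", main = "residuals")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @rdname fit_adherence
#' @param nsim Number of cohorts to simulate from the fitted coefficients.
#' @param seed Integer seed for `simulate()`.
#' @param n_participants Cohort size per simulated cohort (defaults to the
#'   training cohort size).
#' @export
simulate.adherence_fit <- function(object, nsim = 1, seed = 1,
                                   n_participants = NULL, ...) {
  n <- if (is.null(n_participants)) nrow(object$cohort) else n_participants
  preset <- group_preset(attr(object$cohort, "group"), n, object$free_params,
                         n_days = length(object$observed))
  lapply(seq_len(nsim), function(k) {
    simulate_group(preset, object$system, object$decay,
                   seed = derive_seed(seed, k))$cohort
  })
}
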
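#' Ages of past practices at a prediction day
#'
#' Given the days on which self-monitoring was executed, returns the age (in
#' whole days) of every execution strictly before `day`, in execution order
#' (oldest practice first, hence decreasing ages).
#'
#' @param history Integer vector of executed day indices, strictly increasing,
#'   all >= 1. May be empty.
#' @param day Prediction day index (>= 1).
#' @return Integer vector of ages `day - k` for each executed day `k < day`;
#'   empty if there is no prior execution.
#' @examples
#' practice_ages(c(1, 3), 4)    # 3 1
#' practice_ages(integer(0), 1) # empty
#' @export
practice_ages <- function(history, day) {
  history <- validate_history(history)
  if (!is.numeric(day) || length(day) != 1L || is.na(day) || day < 1)
    stop("`day` must be a single day index >= 1", call. = FALSE)
  day <- as.integer(day)
  as.integer(day - history[history < day])
}

validate_history <- function(history) {
  if (length(history) == 0L) return(integer(0))
  if (anyNA(history) || any(history < 1) || any(history != as.integer(history)))
    stop("`history` must contain integer day indices >= 1", call. = FALSE)
  history <- as.integer(history)
  if (is.unsorted(history, strictly = TRUE))
    stop("`history` must be strictly increasing", call. = FALSE)
  history
}

# Per-practice decay exponents for a set of practices described by their ages
# at evaluation time (decreasing = execution order). The exponents depend only
# on the spacing between practices, not on the evaluation day.
practice_decays <- function(ages, decay, sys) {
  k <- length(ages)
  if (decay$mode == "constant") return(rep.int(decay$d_const, k))
  if (k > 1L && any(diff(ages) >= 0))
    stop("ages must be strictly decreasing (distinct practice days)", call. = FALSE)
  d <- numeric(k)
  d[1L] <- sys$a
  if (k >= 2L) {
    for (i in 2:k) {
      j <- seq_len(i - 1L)
      gaps <- ages[j] - ages[i] # ages of earlier practices when practice i is encoded
      m <- log(sum(gaps^(-d[j])))
      d[i] <- sys$c * exp(m) + sys$a
    }
  }
  d
}

#' Base-level activation of the self-monitoring goal
#'
#' Log-power-law base-level learning: `B = ln(sum_i t_i^(-d_i))` over the ages
#' `t_i` of past practices. In constant mode every practice decays with the
#' same exponent `d_const`; in spacing-sensitive mode (default) the i-th
#' practice decays with `d_i = c * exp(m_{i-1}) + a`, where `m_{i-1}` is the
#' base-level activation of the earlier practices evaluated when practice i is
#' encoded (`d_1 = a`), so closely spaced practices are forgotten faster.
#'
#' The empty history (no practice yet) is deliberately an error here: callers
#' apply the empty-history convention, under which the activation term is
#' dropped and total activation falls back to the intercept.
#'
#' @param ages Ages of past practices at the prediction day, in execution
#'   order (decreasing), all >= 1. See [practice_ages()].
#' @param decay An [decay_config()].
#' @param sys An [system_params()].
#' @return Base-level activation (scalar).
#' @examples
#' base_level_activation(1, decay_config("constant", 0.5))   # ln(1) = 0
#' base_level_activation(practice_ages(c(1, 2), 4), decay_config("constant", 0.5))
#' @export
base_level_activation <- function(ages, decay = decay_config(),
                                  sys = system_params()) {
  if (length(ages) == 0L)
    stop("`ages` is empty: apply the empty-history convention in the caller",
         call. = FALSE)
  if (anyNA(ages) || any(ages < 1))
    stop("all ages must be >= 1 whole days", call. = FALSE)
  d <- practice_decays(ages, decay, sys)
  log(sum(ages^(-d)))
}

#' Total activation of the self-monitoring goal
#'
#' Linear form `A = beta0 + beta * B`. The intercept absorbs context
#' (spreading) activation; the slope carries the modelled influence of
#' tailored feedback on the self-monitoring intention.
#'
#' @param B Base-level activation.
#' @param fp An [free_params()].
#' @return Total activation (same shape as `B`).
#' @export
total_activation <- function(B, fp) {
  stopifnot(inherits(fp, "actr_free"))
  fp$beta0 + fp$beta * B
}

#' Goal-retrieval probability
#'
#' Logistic retrieval rule: `P_G = 1 / (1 + exp(-(A - tau) / s))`, strictly
#' increasing in activation, 0.5 at the retrieval threshold.
#'
#' @param A Total activation.
#' @param sys An [system_params()].
#' @return Retrieval probability in `[0, 1]` (vectorized over `A`).
#' @export
retrieval_probability <- function(A, sys = system_params()) {
  stats::plogis((A - sys$tau) / sys$s)
}

#' Goal-success probability after intention-action translation
#'
#' Applies the intention-action transformation to total activation
#' (`A' = Tr * A` by default; `A' = A + Tr` when the system is configured with
#' additive translation) and passes the translated activation through the same
#' logistic rule as retrieval.
#'
#' @inheritParams retrieval_probability
#' @param fp An [free_params()] supplying `Tr`.
#' @return Success probability in `[0, 1]`.
#' @export
goal_success_probability <- function(A, fp, sys = system_params()) {
  stopifnot(inherits(fp, "actr_free"))
  Ap <- if (sys$translation == "multiplicative") fp$Tr * A else A + fp$Tr
  stats::plogis((Ap - sys$tau) / sys$s)
}

#' Utility of the habitual self-monitoring rule over time
#'
#' Delta-rule reinforcement learning with a constant reward per execution:
#' the utility entering day 1 is `U0`, and after each executed day the update
#' `U <- U + alpha * (R0 - U)` takes effect from the next day onward.
#' Non-executed days leave the utility unchanged, so the utility entering day
#' n is `R0 + (U0 - R0) * (1 - alpha)^k(n)` with `k(n)` the number of
#' executions before day n.
#'
#' @param history Executed day indices (strictly increasing, >= 1).
#' @param horizon Number of days to return (>= 1).
#' @param fp An [free_params()] supplying `U0` and `R0`.
#' @param sys An [system_params()] supplying `alpha`.
#' @return Numeric vector of length `horizon`: utility entering each day.
#' @examples
#' fp <- free_params(0, 0, 1, U0 = 0, R0 = 1)
#' utility_trajectory(1:3, 4, fp, system_params(alpha = 0.2))[4]  # 1 - 0.8^3
#' @export
utility_trajectory <- function(history, horizon, fp, sys = system_params()) {
  stopifnot(inherits(fp, "actr_free"))
  history <- validate_history(history)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1)
    stop("`horizon` must be >= 1", call. = FALSE)
  horizon <- as.integer(horizon)
  k <- vapply(seq_len(horizon),
              function(n) sum(history < n), numeric(1))
  fp$R0 + (fp$U0 - fp$R0) * (1 - sys$alpha)^k
}

#' Habit-execution probability
#'
#' Boltzmann selection of the self-monitoring production rule against a
#' competing do-nothing rule of utility 0:
#' `P_H = 1 / (1 + exp(-U / (sqrt(2) * s_u)))`.
#'
#' @param U Utility of the self-monitoring rule.
#' @param sys An [system_params()].
#' @return Selection probability in `[0, 1]` (vectorized over `U`).
#' @export
habit_probability <- function(U, sys = system_params()) {
  stats::plogis(U / (sqrt(2) * sys$s_u))
}

#' Day-by-day model trace for one observed adherence sequence
#'
#' The autoregressive day-ahead predictor: for each day n the model internals
#' are computed from the *observed* history of the sequence restricted to days
#' before n (never from the model's own predictions), and the composite
#' success probability is the two-mechanism mixture
#' `P_SMDB = P_G * P_S + (1 - P_G) * P_H`. Day 1, and any day before the first
#' observed execution, uses the empty-history convention (`A = beta0`,
#' `B` reported as `NA`).
#'
#' @param seq Binary vector (0/1) of observed daily adherence, length >= 1.
#' @param fp An [free_params()].
#' @param sys An [system_params()].
#' @param decay An [decay_config()].
#' @return A data frame with one row per day and columns `day`, `B`, `A`,
#'   `P_G`, `P_S`, `U`, `P_H`, `P_SMDB`, `goal_contrib`, `habit_contrib`.
#' @seealso [mechanism_contributions()], [fit_adherence()]
#' @examples
#' fp <- free_params(1.3, -0.7, 1.9, 0.2, 0.8)
#' predict_sequence(c(1, 0, 1), fp)
#' @export
predict_sequence <- function(seq, fp, sys = system_params(),
                             decay = decay_config()) {
  seq <- validate_binary(seq)
  stopifnot(inherits(fp, "actr_free"))
  n_days <- length(seq)
  execd <- which(seq == 1L)
  U <- utility_trajectory(execd, n_days, fp, sys)
  B <- A <- P_G <- P_S <- P_H <- numeric(n_days)
  for (n in seq_len(n_days)) {
    ages <- n - execd[execd < n]
    if (length(ages) == 0L) {
      B[n] <- NA_real_
      A[n] <- fp$beta0
    } else {
      B[n] <- base_level_activation(ages, decay, sys)
      A[n] <- total_activation(B[n], fp)
    }
    P_G[n] <- retrieval_probability(A[n], sys)
    P_S[n] <- goal_success_probability(A[n], fp, sys)
    P_H[n] <- habit_probability(U[n], sys)
  }
  goal <- P_G * P_S
  habit <- (1 - P_G) * P_H
  data.frame(day = seq_len(n_days), B = B, A = A, P_G = P_G, P_S = P_S,
             U = U, P_H = P_H, P_SMDB = goal + habit,
             goal_contrib = goal, habit_contrib = habit)
}

validate_binary <- function(seq) {
  seq <- unlist(seq, use.names = FALSE)
  if (length(seq) < 1L)
    stop("adherence sequence must have length >= 1", call. = FALSE)
  if (anyNA(seq) || !all(seq %in% c(0, 1)))
    stop("adherence sequence must be binary (0/1)", call. = FALSE)
  as.integer(seq)
}

#' Mechanism contribution curves
#'
#' Splits the composite success probability into the goal-pursuit contribution
#' `P_G * P_S` and the habit-formation contribution `(1 - P_G) * P_H`; their
#' sum equals `P_SMDB` by construction.
#'
#' @param traces Day-trace data frame from [predict_sequence()] (or several
#'   stacked traces).
#' @return Data frame with columns `day`, `goal_contrib`, `habit_contrib`.
#' @export
mechanism_contributions <- function(traces) {
  if (!is.data.frame(traces) || nrow(traces) == 0L)
    stop("`traces` must be a non-empty day-trace data frame", call. = FALSE)
  need <- c("day", "P_G", "P_S", "P_H")
  if (!all(need %in% names(traces)))
    stop("`traces` must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  data.frame(day = traces$day,
             goal_contrib = traces$P_G * traces$P_S,
             habit_contrib = (1 - traces$P_G) * traces$P_H)
}

#' Expected adherence curve of the forward model
#'
#' Monte-Carlo estimate of the model's own expected daily adherence when run
#' generatively (each day's outcome drawn from the model's probability given
#' the simulated history so far). Averages the per-day success probabilities
#' over `n_sim` forward-simulated participants, which is unbiased for the
#' expected adherence and less noisy than averaging the binary outcomes.
#'
#' @param fp An [free_params()].
#' @param sys An [system_params()].
#' @param decay An [decay_config()].
#' @param n_days Horizon in days.
#' @param n_sim Number of simulated participants.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_days`.
#' @export
expected_curve <- function(fp, sys = system_params(), decay = decay_config(),
                           n_days = 21, n_sim = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(n_days)
  for (i in seq_len(n_sim)) {
    acc <- acc + sim_forward(fp, sys, decay, n_days)$p
  }
  acc / n_sim
}
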
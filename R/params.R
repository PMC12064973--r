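#' Fixed architecture parameters of the adherence model
#'
#' Bundles the ACT-R system constants that are held fixed during fitting, as
#' opposed to the five free coefficients estimated per intervention arm (see
#' [free_params()]). These govern the shape of the subsymbolic machinery:
#' memory decay, retrieval noise, utility learning and rule-selection noise.
#'
#' @param c,a Control parameters of the spacing-sensitive decay of base-level
#'   activation: the decay exponent of the i-th practice is
#'   `d_i = c * exp(m_{i-1}) + a`, where `m_{i-1}` is the base-level activation
#'   of the earlier practices at the time practice i is encoded (and
#'   `d_1 = a`). Dimensionless, both >= 0.
#' @param s Activation noise scale of the logistic retrieval rule (> 0).
#' @param s_u Utility noise scale of the Boltzmann rule-selection rule (> 0).
#' @param alpha Learning rate of the delta-rule utility update, in (0, 1].
#' @param tau Retrieval threshold, on the activation scale.
#' @param translation How the intention-action transformation coefficient `Tr`
#'   enters the goal-success probability: `"multiplicative"` (default,
#'   `A' = Tr * A`) or `"additive"` (`A' = A + Tr`).
#'
#' @return An object of class `"actr_system"`: a named list of the validated
#'   constants.
#' @seealso [free_params()], [decay_config()]
#' @examples
#' sys <- system_params()
#' retrieval_probability(sys$tau, sys)  # 0.5 at threshold
#' @export
system_params <- function(c = 0.217, a = 0.177, s = 0.25, s_u = 0.25,
                          alpha = 0.2, tau = 0,
                          translation = c("multiplicative", "additive")) {
  translation <- match.arg(translation)
  vals <- list(c = c, a = a, s = s, s_u = s_u, alpha = alpha, tau = tau)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (s <= 0) stop("activation noise `s` must be > 0", call. = FALSE)
  if (s_u <= 0) stop("utility noise `s_u` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("learning rate `alpha` must lie in (0, 1]", call. = FALSE)
  if (c < 0 || a < 0)
    stop("decay control parameters `c` and `a` must be >= 0", call. = FALSE)
  structure(c(vals, list(translation = translation)), class = "actr_system")
}

#' Free coefficients of the adherence model
#'
#' The five coefficients estimated per intervention arm: the intercept and
#' slope of total activation, the intention-action transformation coefficient,
#' and the initial utility and reward of the habitual self-monitoring rule.
#' None of them is sign-constrained (fitted activation slopes are typically
#' negative, reflecting satiation with accumulated practice).
#'
#' @param beta0 Intercept of total activation (activation units).
#' @param beta Coefficient of base-level activation in total activation; in the
#'   tailored-feedback reading of the model it carries the influence of
#'   feedback on the self-monitoring intention.
#' @param Tr Intention-action transformation coefficient.
#' @param U0 Initial utility of the self-monitoring production rule.
#' @param R0 Reward credited to each execution of the rule (constant-reward
#'   schedule); also the fixed point the utility converges to.
#'
#' @return An object of class `"actr_free"`.
#' @seealso [system_params()], [group_presets()]
#' @examples
#' fp <- free_params(beta0 = 1.3245, beta = -0.6909, Tr = 1.8575,
#'                   U0 = 0.1959, R0 = 0.7983)
#' total_activation(0, fp)  # intercept only when B = 0
#' @export
free_params <- function(beta0, beta, Tr, U0, R0) {
  vals <- list(beta0 = beta0, beta = beta, Tr = Tr, U0 = U0, R0 = R0)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  structure(vals, class = "actr_free")
}

# numeric vector <-> actr_free, in the canonical coefficient order
fp_vector <- function(fp) {
  c(beta0 = fp$beta0, beta = fp$beta, Tr = fp$Tr, U0 = fp$U0, R0 = fp$R0)
}

fp_from_vector <- function(x) {
  x <- unname(as.numeric(x))
  free_params(x[1L], x[2L], x[3L], x[4L], x[5L])
}

#' Decay rule for base-level activation
#'
#' Chooses between the spacing-sensitive decay (per-practice exponents
#' `d_1 = a`, `d_i = c * exp(m_{i-1}) + a`, the Pavlik–Anderson rule) and a
#' constant decay exponent. The constant mode exists mainly as an analytically
#' transparent reference: with `c = 0` the spacing-sensitive rule reduces to it
#' exactly.
#'
#' @param mode `"pavlik_anderson"` (default) or `"constant"`.
#' @param d_const Constant decay exponent (> 0); used only in constant mode.
#' @return An object of class `"actr_decay"`.
#' @export
decay_config <- function(mode = c("pavlik_anderson", "constant"),
                         d_const = 0.5) {
  mode <- match.arg(mode)
  if (!is.numeric(d_const) || length(d_const) != 1L || !is.finite(d_const))
    stop("`d_const` must be a single finite number", call. = FALSE)
  if (mode == "constant" && d_const <= 0)
    stop("`d_const` must be > 0 in constant mode", call. = FALSE)
  structure(list(mode = mode, d_const = d_const), class = "actr_decay")
}

#' @export
print.actr_system <- function(x, ...) {
  cat("ACT-R system parameters\n")
  cat(sprintf("  c = %g, a = %g (decay control), s = %g, s_u = %g (noise)\n",
              x$c, x$a, x$s, x$s_u))
  cat(sprintf("  alpha = %g (learning rate), tau = %g (threshold), translation = %s\n",
              x$alpha, x$tau, x$translation))
  invisible(x)
}

#' @export
print.actr_free <- function(x, ...) {
  cat("Free coefficients:\n")
  print(fp_vector(x))
  invisible(x)
}

#' @export
print.actr_decay <- function(x, ...) {
  if (x$mode == "constant")
    cat(sprintf("Decay: constant, d = %g\n", x$d_const))
  else
    cat("Decay: spacing-sensitive (Pavlik-Anderson)\n")
  invisible(x)
}

#' Synthetic-cohort group preset
#'
#' Describes one simulated intervention arm: its size, model coefficients and
#' the nuisance features of real event logs the generator reproduces (all-zero
#' drop-outs, single-entry days that fail the two-entry adherence rule).
#'
#' @param label Arm label, e.g. `"self_management"`.
#' @param n_participants Number of participants (>= 1).
#' @param free_params An [free_params()] object driving the forward model.
#' @param p_all_zero Fraction of participants forced to an all-zero sequence
#'   (in `[0, 1)`), to exercise the exclusion filter.
#' @param p_single_entry Probability that a non-adherent day still produces
#'   exactly one dietary entry (in `[0, 1]`).
#' @param n_days Sequence length in days (default 21).
#' @return An object of class `"group_preset"`.
#' @seealso [group_presets()], [simulate_group()]
#' @export
group_preset <- function(label, n_participants, free_params,
                         p_all_zero = 0, p_single_entry = 0.2, n_days = 21) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string", call. = FALSE)
  if (!inherits(free_params, "actr_free"))
    stop("`free_params` must be created by free_params()", call. = FALSE)
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L)
    stop("`n_participants` must be >= 1", call. = FALSE)
  if (p_all_zero < 0 || p_all_zero >= 1)
    stop("`p_all_zero` must lie in [0, 1)", call. = FALSE)
  if (p_single_entry < 0 || p_single_entry > 1)
    stop("`p_single_entry` must lie in [0, 1]", call. = FALSE)
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("`n_days` must be >= 1", call. = FALSE)
  structure(list(label = label, n_participants = n_participants,
                 free_params = free_params, p_all_zero = p_all_zero,
                 p_single_entry = p_single_entry, n_days = n_days),
            class = "group_preset")
}

#' Reference presets for the three intervention arms
#'
#' Group presets mirroring the three arms of the 21-day digital weight-loss
#' study design the generator emulates: self-management (n = 49), tailored
#' feedback (n = 23) and intensive support (n = 25), each with the coefficient
#' set estimated for that arm. Group sizes are the retained modelling samples,
#' so `p_all_zero` defaults to 0.
#'
#' @return Named list of three [group_preset()] objects
#'   (`self_management`, `tailored_feedback`, `intensive_support`).
#' @examples
#' pr <- group_presets()
#' pr$self_management$free_params$beta0
#' @export
group_presets <- function() {
  list(
    self_management = group_preset(
      "self_management", 49,
      free_params(beta0 = 1.3245, beta = -0.6909, Tr = 1.8575,
                  U0 = 0.1959, R0 = 0.7983)),
    tailored_feedback = group_preset(
      "tailored_feedback", 23,
      free_params(beta0 = 3.2422, beta = -1.6991, Tr = 3.6615,
                  U0 = 1.9833, R0 = 1.9909)),
    intensive_support = group_preset(
      "intensive_support", 25,
      free_params(beta0 = 3.6510, beta = -2.2174, Tr = 3.1929,
                  U0 = -0.3126, R0 = 4.7796))
  )
}

#' Read and write model parameter files
#'
#' Parameter files are JSON with two top-level objects: `"system"` (the fixed
#' architecture constants plus the decay and translation modes) and `"free"`
#' (the five fitted coefficients).
#'
#' @param system An [system_params()] object.
#' @param free An [free_params()] object.
#' @param decay An [decay_config()] object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly; `read_params_json()`
#'   returns a list with elements `system`, `free` and `decay`.
#' @export
write_params_json <- function(system, free, decay = decay_config(), path) {
  stopifnot(inherits(system, "actr_system"), inherits(free, "actr_free"),
            inherits(decay, "actr_decay"))
  obj <- list(
    system = c(unclass(system),
               list(decay_mode = decay$mode, d_const = decay$d_const)),
    free = unclass(free)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$system) || is.null(obj$free))
    stop("parameter file must contain top-level \"system\" and \"free\" objects",
         call. = FALSE)
  s <- obj$system
  list(
    system = system_params(c = s$c, a = s$a, s = s$s, s_u = s$s_u,
                           alpha = s$alpha, tau = s$tau,
                           translation = s$translation),
    free = do.call(free_params, obj$free[c("beta0", "beta", "Tr", "U0", "R0")]),
    decay = decay_config(mode = s$decay_mode, d_const = s$d_const)
  )
}
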
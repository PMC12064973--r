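pipeline_log <- function(...) message("[actradh] ", sprintf(...))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

pkg_version <- function() as.character(utils::packageVersion("actradh"))

resolve_preset <- function(preset, n = NULL, n_days = NULL) {
  presets <- group_presets()
  alias <- c(sm = "self_management", tf = "tailored_feedback",
             is = "intensive_support")
  if (preset %in% names(alias)) preset <- alias[[preset]]
  if (!preset %in% names(presets))
    stop("unknown preset '", preset, "'; choose one of ",
         paste(c(names(alias), names(presets)), collapse = ", "),
         call. = FALSE)
  p <- presets[[preset]]
  if (!is.null(n)) p$n_participants <- as.integer(n)
  if (!is.null(n_days)) p$n_days <- as.integer(n_days)
  p
}

#' Simulate a study arm and write its artifacts
#'
#' Thin pipeline stage around [simulate_group()]: writes the event-log CSV,
#' the sequence CSV and a manifest JSON echoing every parameter (including the
#' seed and package version) to `out_dir`.
#'
#' @param preset Preset name (`"self_management"`/`"sm"`,
#'   `"tailored_feedback"`/`"tf"`, `"intensive_support"`/`"is"`) or a
#'   [group_preset()] object.
#' @param n,n_days Optional overrides of the preset's size and horizon.
#' @param seed Master seed.
#' @param out_dir Output directory (created if absent).
#' @param sys,decay Architecture configuration.
#' @return Invisibly, a list with the `cohort`, `events` and written `paths`.
#' @export
cmd_simulate <- function(preset, n = NULL, n_days = NULL, seed = 1,
                         out_dir = ".", sys = system_params(),
                         decay = decay_config()) {
  if (is.character(preset)) preset <- resolve_preset(preset, n, n_days)
  if (!inherits(preset, "group_preset"))
    stop("`preset` must be a preset name or a group_preset()", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arm <- simulate_group(preset, sys, decay, seed = seed)
  paths <- list(events = file.path(out_dir, "events.csv"),
                sequences = file.path(out_dir, "sequences.csv"),
                manifest = file.path(out_dir, "simulate_manifest.json"))
  utils::write.csv(arm$events, paths$events, row.names = FALSE, quote = FALSE)
  write_sequences(arm$cohort, paths$sequences)
  write_json_file(list(
    stage = "simulate", seed = seed, version = pkg_version(),
    preset = list(label = preset$label, n_participants = preset$n_participants,
                  p_all_zero = preset$p_all_zero,
                  p_single_entry = preset$p_single_entry,
                  n_days = preset$n_days,
                  free = unclass(preset$free_params)),
    system = unclass(sys), decay = unclass(decay)), paths$manifest)
  pipeline_log("simulate: %d participants x %d days (seed %d) -> %s",
               nrow(arm$cohort), preset$n_days, seed, out_dir)
  invisible(list(cohort = arm$cohort, events = arm$events, paths = paths))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> exclude -> fit -> evaluate -> decompose in
#' order, logging row counts and the seed to standard error and writing every
#' machine-readable artifact to `out_dir`: `sequences.csv`, `events.csv` (when
#' simulating), `retention.json`, `fit.json`, `eval.json`,
#' `fitted_vs_actual.csv`, `residuals.csv`, `decomposition.csv`, `traces.csv`
#' and `manifest.json`. Two runs with the same configuration produce identical
#' files.
#'
#' @param out_dir Output directory.
#' @param preset Preset name or [group_preset()] used to simulate input data;
#'   ignored when `sequences` is given.
#' @param sequences Optional path to an existing sequence CSV (see
#'   [read_sequences()]).
#' @param events Optional path to an event-log CSV; converted with
#'   [build_cohort()].
#' @param group Arm label used when reading `events` or a multi-group
#'   `sequences` file.
#' @param start_date Day-1 date for event-log conversion.
#' @param n,n_days,min_entries Cohort shape and binarization threshold.
#' @param system,decay Architecture configuration.
#' @param control [fit_control()] for the fitting stage.
#' @param B,level,lags Evaluation settings (bootstrap replicates, CI coverage,
#'   Ljung-Box lags).
#' @param seed Master seed; stage seeds are derived from it deterministically.
#' @return Invisibly, a list with `cohort`, `retention`, `fit`, `eval`,
#'   `decomposition` and the written `paths`.
#' @export
run_pipeline <- function(out_dir, preset = "self_management", sequences = NULL,
                         events = NULL, group = NULL,
                         start_date = as.Date("2021-12-01"), n = NULL,
                         n_days = 21, min_entries = 2,
                         system = system_params(), decay = decay_config(),
                         control = fit_control(), B = 1000, level = 0.90,
                         lags = 20, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- acquire ---
  if (!is.null(sequences)) {
    cohort <- read_sequences(sequences, group = group)
    pipeline_log("load: %d sequences from %s", nrow(cohort), sequences)
  } else if (!is.null(events)) {
    ev <- read_event_log(events)
    cohort <- build_cohort(ev, start_date,
                           group = if (is.null(group)) "self_management" else group,
                           n_days = n_days, min_entries = min_entries)
    pipeline_log("build: %d entries -> %d sequences", nrow(ev), nrow(cohort))
  } else {
    sim <- cmd_simulate(preset, n = n, n_days = n_days,
                        seed = derive_seed(seed, 1L), out_dir = out_dir,
                        sys = system, decay = decay)
    cohort <- sim$cohort
    paths <- c(paths, sim$paths)
  }
  paths$sequences_used <- file.path(out_dir, "sequences.csv")
  if (is.null(sequences) && is.null(events)) {
    # already written by cmd_simulate
  } else {
    write_sequences(cohort, paths$sequences_used)
  }

  # --- exclude ---
  excl <- exclude_all_zero(cohort)
  paths$retention <- file.path(out_dir, "retention.json")
  write_json_file(unclass(excl$retention), paths$retention)
  pipeline_log("exclude: enrolled %d, retained %d (%d%% retention), seed %d",
               excl$retention$enrolled, excl$retention$retained,
               excl$retention$retention_pct, seed)

  # --- fit ---
  fit <- fit_adherence(excl$cohort, system, decay, control)
  paths$fit <- file.path(out_dir, "fit.json")
  write_json_file(list(
    group = attr(excl$cohort, "group"),
    coefficients = as.list(fit$coefficients),
    objective = fit$objective, converged = fit$converged,
    n_starts = fit$n_starts, best_start = fit$best_start,
    seed = seed, version = pkg_version()), paths$fit)
  pipeline_log("fit: objective %.6g over %d starts (best #%d)",
               fit$objective, fit$n_starts, fit$best_start)

  # --- evaluate ---
  ev_rep <- evaluate_fit(fit, B = B, level = level, lags = lags,
                         seed = derive_seed(seed, 2L))
  paths$eval <- file.path(out_dir, "eval.json")
  write_json_file(list(
    mse = ev_rep$mse, rmse = ev_rep$rmse, r2 = ev_rep$r2,
    ci_mse = ev_rep$ci_mse, ci_rmse = ev_rep$ci_rmse, ci_r2 = ev_rep$ci_r2,
    lb_stat = ev_rep$lb_stat, lb_p = ev_rep$lb_p, lags = ev_rep$lags,
    level = level, B = B, seed = seed, version = pkg_version()), paths$eval)
  paths$fitted_vs_actual <- file.path(out_dir, "fitted_vs_actual.csv")
  utils::write.csv(ev_rep$fitted_vs_actual, paths$fitted_vs_actual,
                   row.names = FALSE)
  paths$residuals <- file.path(out_dir, "residuals.csv")
  utils::write.csv(ev_rep$residual_table, paths$residuals, row.names = FALSE)
  pipeline_log("evaluate: RMSE %.4f, Ljung-Box p %.3g (B = %d)",
               ev_rep$rmse, ev_rep$lb_p, B)

  # --- decompose ---
  traces <- predict(fit, type = "traces")
  paths$traces <- file.path(out_dir, "traces.csv")
  utils::write.csv(traces, paths$traces, row.names = FALSE)
  agg <- stats::aggregate(traces[c("goal_contrib", "habit_contrib", "P_SMDB")],
                          by = list(day = traces$day), FUN = mean)
  paths$decomposition <- file.path(out_dir, "decomposition.csv")
  utils::write.csv(agg, paths$decomposition, row.names = FALSE)
  pipeline_log("decompose: %d days written", nrow(agg))

  # --- manifest ---
  paths$manifest <- file.path(out_dir, "manifest.json")
  write_json_file(list(
    seed = seed, version = pkg_version(),
    system = unclass(system), decay = unclass(decay),
    fit_control = list(n_starts = control$n_starts, tol = control$tol,
                       max_iter = control$max_iter, seed = control$seed),
    bootstrap = list(B = B, level = level, lags = lags),
    outputs = vapply(paths, basename, character(1))), paths$manifest)

  invisible(list(cohort = excl$cohort, retention = excl$retention, fit = fit,
                 eval = ev_rep, decomposition = agg, paths = paths))
}
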
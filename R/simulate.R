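# Forward (generative) run of the day-ahead model: each day's success
# probability is computed from the SIMULATED history so far, then a Bernoulli
# outcome is drawn. Per-practice decays are maintained incrementally so the
# spacing-sensitive rule matches practice_decays() exactly.
sim_forward <- function(fp, sys, decay, n_days, eps = 0) {
  seqv <- integer(n_days)
  p <- numeric(n_days)
  execd <- integer(0)
  d <- numeric(0)
  sqrt2su <- sqrt(2) * sys$s_u
  for (n in seq_len(n_days)) {
    if (length(execd) == 0L) {
      A <- fp$beta0
    } else {
      ages <- n - execd
      A <- fp$beta0 + fp$beta * log(sum(ages^(-d)))
    }
    P_G <- stats::plogis((A - sys$tau) / sys$s)
    Ap <- if (sys$translation == "multiplicative") fp$Tr * A else A + fp$Tr
    P_S <- stats::plogis((Ap - sys$tau) / sys$s)
    U <- fp$R0 + (fp$U0 - fp$R0) * (1 - sys$alpha)^length(execd)
    P_H <- stats::plogis(U / sqrt2su)
    p[n] <- P_G * P_S + (1 - P_G) * P_H
    p_draw <- if (eps > 0) (1 - eps) * p[n] + eps * 0.5 else p[n]
    y <- stats::rbinom(1L, 1L, p_draw)
    if (y == 1L) {
      d_new <- if (decay$mode == "constant") {
        decay$d_const
      } else if (length(execd) == 0L) {
        sys$a
      } else {
        gaps <- n - execd
        sys$c * exp(log(sum(gaps^(-d)))) + sys$a
      }
      execd <- c(execd, n)
      d <- c(d, d_new)
    }
    seqv[n] <- y
  }
  list(sequence = seqv, p = p)
}

# Emit entry timestamps for one simulated day. Adherent days carry 2-4
# entries; non-adherent days carry one entry with probability p_single_entry
# (a participant who photographed only one meal), else none.
sim_day_entries <- function(adherent, date, p_single_entry) {
  k <- if (adherent) sample(2:4, 1L) else stats::rbinom(1L, 1L, p_single_entry)
  if (k == 0L) return(character(0))
  secs <- sort(floor(stats::runif(k, 0, 86400)))
  secs[secs > 86399] <- 86399
  sprintf("%sT%02d:%02d:%02d", format(date, "%Y-%m-%d"),
          secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
}

#' Simulate one participant's adherence sequence and event log
#'
#' Runs the model generatively (self-consistent forward simulation: each day's
#' success probability is computed from the simulated history so far, and the
#' day's outcome is a Bernoulli draw from it), then emits a plausible dietary
#' event log: 2-4 entries at uniform times on adherent days, at most one entry
#' on non-adherent days. The returned sequence always equals
#' [build_sequence()] applied to the returned log.
#'
#' @param fp An [free_params()].
#' @param sys An [system_params()].
#' @param decay An [decay_config()].
#' @param n_days Horizon in days (default 21).
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param p_single_entry Probability a non-adherent day still has one entry.
#' @param start_date Calendar date of day 1 for the log timestamps.
#' @param id Participant id written into the log.
#' @param eps Misspecification hook: with probability `eps` the day's outcome
#'   is drawn from a fair coin instead of the model (extra Bernoulli noise for
#'   robustness experiments; default 0 = the model itself).
#' @return List with `sequence` (0/1 vector), `log` (data frame
#'   `participant_id`, `timestamp`) and `p` (the per-day success
#'   probabilities used).
#' @examples
#' fp <- group_presets()$self_management$free_params
#' sim <- simulate_participant(fp, seed = 1)
#' identical(sim$sequence, build_sequence(sim$log, "2021-12-01"))
#' @export
simulate_participant <- function(fp, sys = system_params(),
                                 decay = decay_config(), n_days = 21,
                                 seed = NULL, p_single_entry = 0.2,
                                 start_date = as.Date("2021-12-01"),
                                 id = "P001", eps = 0) {
  stopifnot(inherits(fp, "actr_free"))
  if (!is.null(seed)) set.seed(seed)
  start_date <- as.Date(start_date)
  fwd <- sim_forward(fp, sys, decay, n_days, eps = eps)
  stamps <- unlist(lapply(seq_len(n_days), function(n) {
    sim_day_entries(fwd$sequence[n] == 1L, start_date + (n - 1L), p_single_entry)
  }), use.names = FALSE)
  log <- data.frame(participant_id = rep(id, length(stamps)),
                    timestamp = as.character(stamps))
  list(sequence = fwd$sequence, log = log, p = fwd$p)
}

# Deterministic per-participant stream seed derived from the master seed, so
# cohort composition is stable in the participant index when n changes.
derive_seed <- function(seed, i) {
  # arithmetic in doubles (exact below 2^53), reduced into 32-bit seed range
  as.integer(((as.numeric(seed) %% 2147483629) * 48271 + i * 7919) %% 2147483629)
}

#' Simulate a study arm
#'
#' Simulates `n_participants` independent participants from a [group_preset()]
#' (each on its own RNG stream derived from the master seed), forcing the
#' first `round(p_all_zero * n)` of them to all-zero sequences to exercise the
#' exclusion filter. Forced all-zero participants still produce sparse event
#' logs (at most one entry per day), as real drop-outs do.
#'
#' @param preset A [group_preset()].
#' @param sys An [system_params()].
#' @param decay An [decay_config()].
#' @param seed Master integer seed.
#' @param start_date Calendar date of day 1.
#' @param eps Misspecification noise passed to [simulate_participant()].
#' @return List with `cohort` (an [adherence_cohort()]), `events` (combined
#'   event-log data frame) and `seed`.
#' @examples
#' arm <- simulate_group(group_presets()$tailored_feedback, seed = 1)
#' count_outcome_events(arm$cohort)  # 23 * 21
#' @export
simulate_group <- function(preset, sys = system_params(),
                           decay = decay_config(), seed = 1,
                           start_date = as.Date("2021-12-01"), eps = 0) {
  if (!inherits(preset, "group_preset"))
    stop("`preset` must be created by group_preset()", call. = FALSE)
  n <- preset$n_participants
  n_zero <- round(preset$p_all_zero * n)
  ids <- sprintf("%s_%03d", preset$label, seq_len(n))
  m <- matrix(0L, n, preset$n_days)
  logs <- vector("list", n)
  start_date <- as.Date(start_date)
  for (i in seq_len(n)) {
    pseed <- derive_seed(seed, i)
    if (i <= n_zero) {
      set.seed(pseed)
      stamps <- unlist(lapply(seq_len(preset$n_days), function(nd) {
        sim_day_entries(FALSE, start_date + (nd - 1L), preset$p_single_entry)
      }), use.names = FALSE)
      logs[[i]] <- data.frame(participant_id = rep(ids[i], length(stamps)),
                              timestamp = as.character(stamps))
    } else {
      sim <- simulate_participant(preset$free_params, sys, decay,
                                  n_days = preset$n_days, seed = pseed,
                                  p_single_entry = preset$p_single_entry,
                                  start_date = start_date, id = ids[i],
                                  eps = eps)
      m[i, ] <- sim$sequence
      logs[[i]] <- sim$log
    }
  }
  list(cohort = adherence_cohort(m, group = preset$label, ids = ids),
       events = do.call(rbind, logs),
       seed = seed)
}
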
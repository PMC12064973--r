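#' Cohort of binary adherence sequences
#'
#' A cohort is a participants-by-days binary matrix with unique participant
#' ids as row names and a study-arm label attached. All downstream stages
#' (fitting, evaluation, bootstrap) operate on this container.
#'
#' @param days Matrix or data frame of 0/1 values, one row per participant,
#'   one column per day.
#' @param group Arm label (single string); canonical labels are
#'   `"self_management"`, `"tailored_feedback"` and `"intensive_support"`.
#' @param ids Optional character vector of participant ids (unique); defaults
#'   to existing row names or `P001, P002, ...`.
#' @return An object of class `"adherence_cohort"` (a classed binary matrix).
#' @examples
#' coh <- adherence_cohort(rbind(c(1, 0, 1), c(1, 1, 0)), "self_management")
#' group_adherence_curve(coh)
#' @export
adherence_cohort <- function(days, group = "self_management", ids = NULL) {
  m <- as.matrix(days)
  storage.mode(m) <- "integer"
  if (ncol(m) < 1L) stop("cohort must have at least one day column", call. = FALSE)
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("adherence values must be binary (0/1)", call. = FALSE)
  if (is.null(ids)) {
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(m)))
  }
  if (length(ids) != nrow(m) || anyDuplicated(ids))
    stop("participant ids must be unique and match the number of rows",
         call. = FALSE)
  if (!is.character(group) || length(group) != 1L || !nzchar(group))
    stop("`group` must be a single non-empty string", call. = FALSE)
  rownames(m) <- ids
  colnames(m) <- sprintf("d%d", seq_len(ncol(m)))
  structure(m, group = group, class = c("adherence_cohort", "matrix", "array"))
}

cohort_matrix <- function(cohort) {
  if (!inherits(cohort, "adherence_cohort"))
    stop("expected an `adherence_cohort` object", call. = FALSE)
  m <- unclass(cohort)
  attr(m, "group") <- NULL
  m
}

#' @export
print.adherence_cohort <- function(x, ...) {
  m <- cohort_matrix(x)
  cat(sprintf("Adherence cohort '%s': %d participants x %d days\n",
              attr(x, "group"), nrow(m), ncol(m)))
  if (nrow(m) > 0L)
    cat(sprintf("  mean adherence %.3f\n", mean(m)))
  invisible(x)
}

#' Read a dietary-entry event log
#'
#' Event logs are comma-separated UTF-8 files with a header row and columns
#' `participant_id` and `timestamp` (ISO-8601, e.g.
#' `2021-12-01T08:30:00`). Each row is one uploaded dietary entry; duplicates
#' are legitimate (two photos in one minute are two entries).
#'
#' @param path CSV path.
#' @return Data frame with character columns `participant_id` and `timestamp`,
#'   validated to parse as timestamps.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("participant_id", "timestamp")
  if (!all(need %in% names(df)))
    stop("event log must have columns participant_id and timestamp",
         call. = FALSE)
  parse_timestamps(df$timestamp)
  df[need]
}

# Returns POSIXct; errors naming the first offending row. Formats are tried
# per element (a single malformed row must not poison the others).
parse_timestamps <- function(x, tz = "UTC") {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (f in fmts) {
    todo <- which(is.na(ts))
    if (length(todo) == 0L) break
    ts[todo] <- as.POSIXct(strptime(x[todo], f, tz = tz), tz = tz)
  }
  bad <- which(is.na(ts) | is.na(x))
  if (length(bad) > 0L)
    stop(sprintf("malformed timestamp in row %d: \"%s\"", bad[1L], x[bad[1L]]),
         call. = FALSE)
  ts
}

#' Binarize one participant's event log into a daily adherence sequence
#'
#' Day n of the sequence is 1 when at least `min_entries` dietary entries fall
#' on the calendar date `start_date + (n - 1)`, else 0. Entries outside the
#' `[start_date, start_date + n_days - 1]` window are ignored. The default
#' threshold of two entries per day encodes the study's adherence rule.
#'
#' @param log Data frame with a `timestamp` column (one participant's entries),
#'   or the list returned by [simulate_participant()].
#' @param start_date Day 1 of the observation window (`Date` or `"YYYY-MM-DD"`);
#'   in the study design this is the first day after the preparation week.
#' @param n_days Sequence length (default 21).
#' @param min_entries Minimum entries for an adherent day (default 2).
#' @param tz Timezone used to assign calendar dates to timestamps; the default
#'   `"UTC"` takes the date component literally, with no conversion.
#' @return Integer 0/1 vector of length `n_days`.
#' @examples
#' log <- data.frame(participant_id = "P1",
#'                   timestamp = c("2021-12-01T08:00:00", "2021-12-01T19:30:00",
#'                                 "2021-12-02T12:00:00"))
#' build_sequence(log, "2021-12-01", n_days = 3)  # 1 0 0
#' @export
build_sequence <- function(log, start_date, n_days = 21, min_entries = 2,
                           tz = "UTC") {
  if (is.list(log) && !is.null(log$log)) log <- log$log
  if (!is.data.frame(log) || !"timestamp" %in% names(log))
    stop("`log` must be a data frame with a `timestamp` column", call. = FALSE)
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("`n_days` must be >= 1", call. = FALSE)
  if (min_entries < 1) stop("`min_entries` must be >= 1", call. = FALSE)
  start_date <- as.Date(start_date)
  if (nrow(log) == 0L) return(integer(n_days))
  ts <- parse_timestamps(log$timestamp, tz = tz)
  idx <- as.integer(as.Date(ts, tz = tz) - start_date) + 1L
  idx <- idx[idx >= 1L & idx <= n_days]
  counts <- tabulate(idx, nbins = n_days)
  as.integer(counts >= min_entries)
}

#' Build a cohort from a multi-participant event log
#'
#' Applies [build_sequence()] per participant (rows grouped by
#' `participant_id`, first-appearance order preserved).
#'
#' @param events Event-log data frame (`participant_id`, `timestamp`) as read
#'   by [read_event_log()].
#' @param group Arm label for the cohort.
#' @inheritParams build_sequence
#' @return An [adherence_cohort()].
#' @export
build_cohort <- function(events, start_date, group = "self_management",
                         n_days = 21, min_entries = 2, tz = "UTC") {
  if (!all(c("participant_id", "timestamp") %in% names(events)))
    stop("`events` must have columns participant_id and timestamp", call. = FALSE)
  ids <- unique(events$participant_id)
  m <- t(vapply(ids, function(id) {
    build_sequence(events[events$participant_id == id, , drop = FALSE],
                   start_date, n_days, min_entries, tz)
  }, integer(n_days)))
  if (n_days == 1L) m <- matrix(m, ncol = 1L) # vapply drops to vector symmetry
  adherence_cohort(m, group = group, ids = ids)
}

#' Exclude participants with all-zero sequences
#'
#' Sequences with 21 consecutive zero days carry no temporal variance and are
#' removed before modelling. The retention report mirrors the study's
#' accounting: enrolled, retained, excluded and retention percentage rounded
#' to the nearest integer.
#'
#' @param cohort An [adherence_cohort()].
#' @return List with elements `cohort` (the filtered cohort) and `retention`
#'   (class `"retention_report"`: `group`, `enrolled`, `retained`, `excluded`,
#'   `retention_pct`).
#' @examples
#' coh <- adherence_cohort(rbind(c(0, 0, 0), c(1, 0, 1)), "self_management")
#' exclude_all_zero(coh)$retention
#' @export
exclude_all_zero <- function(cohort) {
  m <- cohort_matrix(cohort)
  keep <- rowSums(m) > 0L
  if (!any(keep))
    stop("all participants have all-zero sequences; the cohort is empty after exclusion",
         call. = FALSE)
  report <- structure(
    list(group = attr(cohort, "group"),
         enrolled = nrow(m),
         retained = sum(keep),
         excluded = sum(!keep),
         retention_pct = as.integer(round(100 * sum(keep) / nrow(m)))),
    class = "retention_report")
  list(cohort = adherence_cohort(m[keep, , drop = FALSE],
                                 group = attr(cohort, "group"),
                                 ids = rownames(m)[keep]),
       retention = report)
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("Group %s: enrolled %d, retained %d (%d%% retention), excluded %d\n",
              x$group, x$enrolled, x$retained, x$retention_pct, x$excluded))
  invisible(x)
}

#' Daily group adherence curve
#'
#' The proportion of participants adherent on each day — the group-level
#' series the model is fitted to.
#'
#' @param cohort An [adherence_cohort()] with at least one participant.
#' @return Numeric vector of length `n_days`, each element in `[0, 1]`.
#' @export
group_adherence_curve <- function(cohort) {
  m <- cohort_matrix(cohort)
  if (nrow(m) == 0L) stop("cohort is empty", call. = FALSE)
  unname(colMeans(m))
}

#' Outcome-event count of a cohort
#'
#' The number of predicted binary outcomes: sequence length times the number
#' of participants, the quantity used for rule-of-thumb sample-size
#' accounting in prediction-model reporting.
#'
#' @param cohort An [adherence_cohort()].
#' @return Integer count (0 for an empty cohort).
#' @export
count_outcome_events <- function(cohort) {
  m <- cohort_matrix(cohort)
  nrow(m) * ncol(m)
}

#' Per-participant and group mean adherence
#'
#' @param cohort An [adherence_cohort()] with at least one participant.
#' @return List with `rates` (named per-participant row means), `mean` and
#'   `sd` of the per-participant rates.
#' @export
mean_adherence <- function(cohort) {
  m <- cohort_matrix(cohort)
  if (nrow(m) == 0L) stop("cohort is empty", call. = FALSE)
  rates <- rowMeans(m)
  list(rates = rates, mean = mean(rates), sd = stats::sd(rates))
}

#' Read and write adherence sequence files
#'
#' Wide CSV dialect: columns `participant_id`, `group`, then `d1 ... dT` with
#' 0/1 values.
#'
#' @param cohort An [adherence_cohort()].
#' @param path CSV path.
#' @param group When reading a file containing several group labels, the label
#'   to keep; may be omitted for single-group files.
#' @return `write_sequences()` returns `path` invisibly; `read_sequences()`
#'   returns an [adherence_cohort()].
#' @export
write_sequences <- function(cohort, path) {
  m <- cohort_matrix(cohort)
  df <- data.frame(participant_id = rownames(m),
                   group = attr(cohort, "group"),
                   m, check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path, group = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("participant_id", "group") %in% names(df)))
    stop("sequence file must have participant_id and group columns", call. = FALSE)
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  labels <- unique(df$group)
  if (length(labels) != 1L)
    stop("sequence file holds ", length(labels),
         " group labels; pass `group` to select one", call. = FALSE)
  daycols <- grep("^d[0-9]+$", names(df), value = TRUE)
  daycols <- daycols[order(as.integer(sub("^d", "", daycols)))]
  adherence_cohort(df[daycols], group = labels, ids = df$participant_id)
}
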
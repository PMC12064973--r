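make_log <- function(stamps, id = "P1") {
  data.frame(participant_id = rep(id, length(stamps)), timestamp = stamps)
}

test_that("the two-entries-per-day rule binarizes event logs", {
  log <- make_log(c("2021-12-01T08:00:00", "2021-12-01T19:30:00",  # day 1: 2 entries
                    "2021-12-02T12:00:00",                          # day 2: 1 entry
                    "2021-12-04T07:00:00", "2021-12-04T07:00:00",   # day 4: duplicates count
                    "2021-11-30T23:59:59", "2021-12-06T10:00:00"))  # outside window
  expect_identical(build_sequence(log, "2021-12-01", n_days = 5),
                   c(1L, 0L, 0L, 1L, 0L))
  # empty log
  expect_identical(build_sequence(make_log(character(0)), "2021-12-01", 4),
                   integer(4))
  # threshold is configurable
  expect_identical(build_sequence(log, "2021-12-01", n_days = 5, min_entries = 1),
                   c(1L, 1L, 0L, 1L, 0L))
  # row order is irrelevant
  set.seed(2)
  shuffled <- log[sample.int(nrow(log)), , drop = FALSE]
  expect_identical(build_sequence(shuffled, "2021-12-01", n_days = 5),
                   build_sequence(log, "2021-12-01", n_days = 5))
})

test_that("malformed timestamps are reported with their row", {
  log <- make_log(c("2021-12-01T08:00:00", "yesterday-ish", "2021-12-02T09:00:00"))
  expect_error(build_sequence(log, "2021-12-01", 3), "row 2.*yesterday-ish")
})

test_that("event-log CSV round-trips through read_event_log and build_cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(make_log(c("2021-12-01T08:00:00", "2021-12-01T09:00:00"), "a"),
              make_log(c("2021-12-02T10:00:00",
                         "2021-12-03T10:00:00", "2021-12-03T11:00:00"), "b"))
  utils::write.csv(df, path, row.names = FALSE)
  ev <- read_event_log(path)
  expect_identical(ev$participant_id, df$participant_id)
  coh <- build_cohort(ev, "2021-12-01", n_days = 3, group = "tailored_feedback")
  expect_identical(unname(as.matrix(coh)[, 1]), c(1L, 0L))
  expect_identical(unname(as.matrix(coh)[, 3]), c(0L, 1L))
  expect_identical(attr(coh, "group"), "tailored_feedback")
  expect_error(read_event_log({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), p, row.names = FALSE); p
  }), "participant_id")
})

test_that("the all-zero exclusion filter reproduces enrolment accounting", {
  seq1 <- c(1L, rep(0L, 20))
  mk <- function(n_keep, n_zero, group) {
    m <- rbind(matrix(rep(seq1, n_keep), ncol = 21, byrow = TRUE),
               matrix(0L, n_zero, 21))
    adherence_cohort(m, group = group)
  }
  r1 <- exclude_all_zero(mk(49, 17, "self_management"))$retention
  expect_identical(c(r1$enrolled, r1$retained, r1$retention_pct),
                   c(66L, 49L, 74L))
  r2 <- exclude_all_zero(mk(23, 1, "tailored_feedback"))$retention
  expect_identical(c(r2$enrolled, r2$retained, r2$retention_pct),
                   c(24L, 23L, 96L))
  r3 <- exclude_all_zero(mk(25, 0, "intensive_support"))$retention
  expect_identical(c(r3$enrolled, r3$retained, r3$retention_pct),
                   c(25L, 25L, 100L))
  expect_error(exclude_all_zero(adherence_cohort(matrix(0L, 3, 21))), "empty")
})

test_that("exclusion keeps every participant with at least one adherent day", {
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(stats::rbinom(60, 1, 0.15), 10, 6)
    m[1, ] <- 1L # guarantee a survivor
    coh <- adherence_cohort(m)
    out <- exclude_all_zero(coh)
    expect_identical(out$retention$enrolled,
                     out$retention$retained + out$retention$excluded)
    expect_true(all(rowSums(as.matrix(out$cohort)) > 0))
    expect_setequal(rownames(out$cohort),
                    rownames(coh)[rowSums(m) > 0])
  }
})

test_that("group adherence curve equals the column means of the cohort", {
  expect_equal(group_adherence_curve(adherence_cohort(matrix(1L, 4, 5))),
               rep(1, 5))
  one <- adherence_cohort(matrix(c(1L, 0L, 1L), 1, 3))
  expect_equal(group_adherence_curve(one), c(1, 0, 1))
  two <- adherence_cohort(rbind(c(1L, 0L), c(1L, 1L)))
  expect_equal(group_adherence_curve(two), c(1, 0.5))
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(stats::rbinom(40, 1, 0.5), 5, 8)
    expect_equal(group_adherence_curve(adherence_cohort(m)),
                 apply(m, 2, mean))
  }
  expect_error(group_adherence_curve(adherence_cohort(matrix(0L, 0, 5))),
               "empty")
})

test_that("outcome-event counts depend only on cohort shape", {
  expect_identical(count_outcome_events(adherence_cohort(matrix(0L, 49, 21))),
                   1029L)
  expect_identical(count_outcome_events(adherence_cohort(matrix(1L, 25, 21))),
                   525L)
  expect_identical(count_outcome_events(adherence_cohort(matrix(0L, 0, 21))), 0L)
  set.seed(4)
  m <- matrix(stats::rbinom(23 * 21, 1, 0.5), 23, 21)
  expect_identical(count_outcome_events(adherence_cohort(m)), 483L)
})

test_that("mean adherence summarises per-participant rates", {
  allones <- mean_adherence(adherence_cohort(matrix(1L, 3, 21)))
  expect_equal(allones$mean, 1)
  expect_equal(allones$sd, 0)
  single <- mean_adherence(adherence_cohort(matrix(1L, 1, 21)))
  expect_equal(unname(single$rates), 1)
  two <- mean_adherence(adherence_cohort(rbind(c(1L, 0L), c(1L, 1L))))
  expect_equal(two$mean, 0.75)
})

test_that("sequence CSV round-trips", {
  coh <- rand_cohort(n = 5, n_days = 21, group = "intensive_support")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequences(coh, path)
  back <- read_sequences(path)
  expect_identical(as.matrix(back), as.matrix(coh))
  expect_identical(attr(back, "group"), "intensive_support")
  expect_identical(rownames(back), rownames(coh))
})

test_that("cohort validation rejects malformed input", {
  expect_error(adherence_cohort(matrix(c(0, 2), 1, 2)), "binary")
  expect_error(adherence_cohort(matrix(0L, 2, 2), ids = c("a", "a")), "unique")
  expect_error(adherence_cohort(matrix(0L, 2, 2), group = ""), "non-empty")
})
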
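test_that("practice ages are day-minus-execution, in execution order", {
  expect_identical(practice_ages(c(1, 3), 4), c(3L, 1L))
  expect_identical(practice_ages(integer(0), 1), integer(0))
  expect_identical(practice_ages(c(1, 2, 5), 6), c(5L, 4L, 1L))
  # executions on or after the prediction day are not part of the history
  expect_identical(practice_ages(c(1, 4, 9), 4), 3L)
  expect_error(practice_ages(c(1, 3), 0), "day")
  expect_error(practice_ages(c(3, 1), 5), "increasing")
})

test_that("base-level activation follows the log power law (constant mode)", {
  expect_equal(base_level_activation(1, const_decay(0.5)), 0)
  expect_equal(base_level_activation(c(2, 1), const_decay(0.5)),
               log(1 + 2^-0.5))
  expect_error(base_level_activation(integer(0), const_decay()), "empty")
  expect_error(base_level_activation(c(2, 0.5), const_decay()), ">= 1")

  # brute-force direct-summation oracle on random histories over a 21-day window
  set.seed(31)
  for (rep in 1:50) {
    hist <- rand_history()
    if (length(hist) == 0) next
    day <- max(hist) + sample.int(5, 1)
    d <- stats::runif(1, 0.1, 1.5)
    ages <- practice_ages(hist, day)
    oracle <- 0
    for (a in ages) oracle <- oracle + a^(-d)
    expect_equal(base_level_activation(ages, const_decay(d)), log(oracle),
                 tolerance = 1e-12)
  }
})

test_that("adding practices at fixed ages never decreases activation", {
  set.seed(77)
  for (rep in 1:25) {
    ages <- sort(sample.int(20, sample(2:8, 1)), decreasing = TRUE)
    d <- const_decay(stats::runif(1, 0.2, 1))
    sub <- sort(sample(seq_along(ages), length(ages) - 1), decreasing = FALSE)
    expect_gte(base_level_activation(ages, d),
               base_level_activation(ages[sub], d))
  }
})

test_that("spacing-sensitive decay with c = 0 is identical to constant decay", {
  sys0 <- system_params(c = 0, a = 0.42)
  set.seed(5)
  for (rep in 1:20) {
    hist <- rand_history()
    if (length(hist) == 0) next
    ages <- practice_ages(hist, max(hist) + 1L)
    expect_identical(
      base_level_activation(ages, decay_config("pavlik_anderson"), sys0),
      base_level_activation(ages, const_decay(0.42), sys0))
  }
  # and with c > 0 massed practice decays faster than spaced practice
  sys1 <- system_params()
  massed <- base_level_activation(c(3, 2, 1), decay_config(), sys1)
  spaced <- base_level_activation(c(15, 8, 1), decay_config(), sys1)
  d_massed <- actradh:::practice_decays(c(3, 2, 1), decay_config(), sys1)
  d_spaced <- actradh:::practice_decays(c(15, 8, 1), decay_config(), sys1)
  expect_gt(d_massed[3], d_spaced[3])
  expect_true(is.finite(massed) && is.finite(spaced))
})

test_that("activation and probability primitives obey their closed forms", {
  sys <- system_params()
  fp_sm <- free_params(1.3245, -0.6909, 1.8575, 0.1959, 0.7983)
  expect_equal(total_activation(0, fp_sm), 1.3245)
  expect_equal(total_activation(3, free_params(0.4, 0, 1, 0, 0)), 0.4)
  expect_equal(total_activation(1, free_params(0, 2, 1, 0, 0)), 2)

  expect_equal(retrieval_probability(sys$tau, sys), 0.5)
  expect_equal(retrieval_probability(sys$tau + sys$s * log(9), sys), 0.9)
  expect_equal(retrieval_probability(1e6, sys), 1)

  # Tr = 1 makes translation the identity
  fp1 <- free_params(0, 0, 1, 0, 0)
  A <- seq(-2, 2, by = 0.5)
  expect_equal(goal_success_probability(A, fp1, sys),
               retrieval_probability(A, sys))
  # midpoint when the translated activation hits the threshold
  sys_t <- system_params(tau = 0.3)
  expect_equal(goal_success_probability(0.6, free_params(0, 0, 0.5, 0, 0), sys_t),
               0.5)
  fp_tf <- free_params(0, 0, 3.6615, 0, 0)
  expect_equal(goal_success_probability(1, fp_tf, system_params(tau = 0, s = 0.25)),
               1 / (1 + exp(-3.6615 / 0.25)))
  # additive translation variant
  sys_add <- system_params(translation = "additive")
  expect_equal(goal_success_probability(0.4, free_params(0, 0, -0.4, 0, 0), sys_add),
               0.5)

  expect_equal(habit_probability(0, sys), 0.5)
  u <- stats::rnorm(10)
  expect_equal(habit_probability(u, sys) + habit_probability(-u, sys),
               rep(1, 10))
  expect_equal(habit_probability(1e6, sys), 1)
})

test_that("utility follows the delta rule with constant reward", {
  sys <- system_params(alpha = 0.2)
  fp <- free_params(0, 0, 1, U0 = 0, R0 = 1)
  expect_equal(utility_trajectory(integer(0), 5, free_params(0, 0, 1, 0.7, 2), sys),
               rep(0.7, 5))
  expect_equal(utility_trajectory(1, 2, free_params(0, 0, 1, 0, 3),
                                  system_params(alpha = 1))[2], 3)
  # hand recursion oracle
  U <- 0
  for (day in 1:3) U <- U + 0.2 * (1 - U)
  got <- utility_trajectory(1:3, 4, fp, sys)
  expect_equal(got[4], U)
  expect_equal(got[4], 0.488)
  # fixed point: U0 = R0 leaves utility constant
  fp_fix <- free_params(0, 0, 1, U0 = 1.3, R0 = 1.3)
  expect_equal(utility_trajectory(1:10, 11, fp_fix, sys), rep(1.3, 11))
  # convergence to R0 after many updates, any learning rate in (0, 1]
  for (alpha in c(0.05, 0.2, 1)) {
    tr <- utility_trajectory(1:1000, 1001, free_params(0, 0, 1, -4, 2.5),
                             system_params(alpha = alpha))
    expect_lt(abs(tr[1001] - 2.5), 1e-6)
  }
})

test_that("day-ahead traces match a fully hand-stepped computation", {
  fp <- toy_fp()
  sys <- system_params()
  dec <- const_decay(0.5)
  tr <- predict_sequence(c(1, 0, 1), fp, sys, dec)

  # independent arithmetic, straight from the formulas
  lgs <- function(x) 1 / (1 + exp(-x))
  ph <- function(U) lgs(U / (sqrt(2) * 0.25))
  day <- function(A, U) {
    pg <- lgs((A - 0) / 0.25)
    ps <- lgs((1.9 * A - 0) / 0.25)
    c(A = A, P_G = pg, P_S = ps, P_H = ph(U),
      P = pg * ps + (1 - pg) * ph(U))
  }
  d1 <- day(1.3, 0.2)                                  # empty history
  d2 <- day(1.3 + (-0.7) * log(1^-0.5), 0.2 + 0.2 * (0.8 - 0.2))
  d3 <- day(1.3 + (-0.7) * log(2^-0.5), 0.2 + 0.2 * (0.8 - 0.2))

  expect_equal(tr$A, c(d1["A"], d2["A"], d3["A"]), ignore_attr = TRUE)
  expect_equal(tr$P_G, c(d1["P_G"], d2["P_G"], d3["P_G"]), ignore_attr = TRUE)
  expect_equal(tr$P_S, c(d1["P_S"], d2["P_S"], d3["P_S"]), ignore_attr = TRUE)
  expect_equal(tr$P_H, c(d1["P_H"], d2["P_H"], d3["P_H"]), ignore_attr = TRUE)
  expect_equal(tr$P_SMDB, c(d1["P"], d2["P"], d3["P"]), ignore_attr = TRUE)
  expect_true(is.na(tr$B[1]))
  expect_error(predict_sequence(c(1, 2, 0), fp), "binary")
})

test_that("the composite probability is a convex mixture of the two routes", {
  sys <- system_params()
  # saturated goal retrieval: the goal route decides everything
  fp_hi <- free_params(1e4, 0, 1.5, -0.3, 0.5)
  tr_hi <- predict_sequence(c(1, 0, 1, 1, 0), fp_hi, sys)
  expect_equal(tr_hi$P_SMDB, tr_hi$P_S, tolerance = 1e-9)
  expect_equal(tr_hi$habit_contrib, rep(0, 5), tolerance = 1e-9)
  # suppressed retrieval: the habit route decides everything
  fp_lo <- free_params(-1e4, 0, 1.5, -0.3, 0.5)
  tr_lo <- predict_sequence(c(1, 0, 1, 1, 0), fp_lo, sys)
  expect_equal(tr_lo$P_SMDB, tr_lo$P_H, tolerance = 1e-9)

  set.seed(99)
  for (rep in 1:30) {
    fp <- rand_fp()
    seqv <- stats::rbinom(10, 1, 0.5)
    tr <- predict_sequence(seqv, fp, sys)
    probs <- unlist(tr[c("P_G", "P_S", "P_H", "P_SMDB")])
    expect_true(all(probs >= 0 & probs <= 1))
    expect_lt(max(abs(tr$P_SMDB - (tr$goal_contrib + tr$habit_contrib))), 1e-12)
    # deterministic re-evaluation
    expect_identical(tr, predict_sequence(seqv, fp, sys))
  }
})

test_that("mechanism contributions split and re-sum the composite probability", {
  tr <- predict_sequence(c(1, 1, 0, 1), toy_fp())
  mc <- mechanism_contributions(tr)
  expect_equal(mc$goal_contrib + mc$habit_contrib, tr$P_SMDB, tolerance = 1e-12)
  fake <- data.frame(day = 1, P_G = 0.5, P_S = 0.8, P_H = 0.4)
  mc2 <- mechanism_contributions(fake)
  expect_equal(c(mc2$goal_contrib, mc2$habit_contrib), c(0.4, 0.2))
  fake$P_G <- 1
  expect_equal(mechanism_contributions(fake)$habit_contrib, 0)
  expect_error(mechanism_contributions(data.frame()), "non-empty")
})

test_that("retrieval and habit probabilities are strictly monotone", {
  sys <- system_params()
  A <- sort(stats::rnorm(50, sd = 3))
  expect_true(all(diff(retrieval_probability(A, sys)) > 0))
  expect_true(all(diff(habit_probability(A, sys)) > 0))
})
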
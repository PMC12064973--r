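# Shared fixtures: small parameter sets and cohort builders used across the
# suite. Everything is generated in code; no stored data.

toy_fp <- function() free_params(beta0 = 1.3, beta = -0.7, Tr = 1.9,
                                 U0 = 0.2, R0 = 0.8)

const_decay <- function(d = 0.5) decay_config("constant", d_const = d)

# random free parameters on the plausible coefficient scale
rand_fp <- function() {
  free_params(stats::runif(1, -3, 3), stats::runif(1, -3, 3),
              stats::runif(1, -2, 4), stats::runif(1, -3, 3),
              stats::runif(1, -1, 4))
}

# random practice history within an n-day window (possibly empty)
rand_history <- function(n_days = 21, max_len = 10) {
  len <- sample(0:max_len, 1)
  sort(sample.int(n_days, min(len, n_days)))
}

# random binary cohort with no all-zero rows
rand_cohort <- function(n = 6, n_days = 8, p = 0.4,
                        group = "self_management") {
  m <- matrix(stats::rbinom(n * n_days, 1, p), n, n_days)
  zero <- rowSums(m) == 0
  m[zero, sample.int(n_days, 1)] <- 1L
  adherence_cohort(m, group = group)
}
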
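Package: actradh
Title: Goal-Pursuit and Habit-Formation Dynamics of Dietary Self-Monitoring Adherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic modelling of daily adherence to self-monitoring of dietary
    behaviours in digital weight-loss interventions, built on the subsymbolic
    computations of the ACT-R cognitive architecture. Adherence on each day is
    the outcome of two competing routes: deliberate goal pursuit, driven by the
    activation of the self-monitoring goal in declarative memory (log-power-law
    base-level learning with spacing-sensitive decay), and habitual execution,
    driven by the reinforcement-learned utility of the self-monitoring
    production rule. The package provides the day-ahead autoregressive
    predictor, group-level fitting of the five free coefficients by multi-start
    BFGS, bootstrap confidence intervals and Ljung-Box residual diagnostics,
    mechanism decomposition curves, event-log to binary-sequence conversion
    with the two-entries-per-day rule, and a self-consistent synthetic cohort
    generator for the three intervention arms (self-management, tailored
    feedback, intensive support).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
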
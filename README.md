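# actradh

Dynamic modelling of adherence to **self-monitoring of dietary behaviours
(SMDB)** in digital weight-loss interventions, built on the subsymbolic
computations of the ACT-R cognitive architecture. The package is aimed at
researchers in computational behavioural science and mHealth who want to move
beyond descriptive adherence curves: it turns a cohort's daily 0/1 recording
sequences into a fitted mechanistic model that separates *deliberate goal
pursuit* from *habitual execution*, and quantifies how each mechanism's
contribution evolves over a 21-day intervention.

## The model

For each participant and day $n$, the probability of successfully recording
the diet is a mixture of two routes:

$$P_{SMDB}(n) = P_G(n)\,P_S(n) + \bigl(1 - P_G(n)\bigr)\,P_H(n)$$

**Goal pursuit** — the SMDB goal is a declarative-memory chunk whose
base-level activation summarises past practice,
$B(n) = \ln \sum_i t_i^{-d_i}$, with $t_i$ the age in days of the $i$-th past
execution and spacing-sensitive decay $d_1 = a$, $d_i = c\,e^{m_{i-1}} + a$.
Total activation is $A = \beta_0 + \beta B$; the goal is retrieved with
probability $P_G = \sigma((A-\tau)/s)$ and translated into action with
probability $P_S = \sigma((Tr\,A-\tau)/s)$.

**Habit formation** — the SMDB production rule carries a utility updated by
the delta rule $U \leftarrow U + \alpha(R_0 - U)$ after each execution
(initial value $U_0$), and fires habitually with Boltzmann probability
$P_H = \sigma(U/(\sqrt2\,s_u))$ against a do-nothing rule of utility 0.

The predictor is autoregressive: day-$n$ quantities are computed from the
*observed* history on days $< n$. The five free coefficients
$(\beta_0, \beta, Tr, U_0, R_0)$ are fitted per intervention arm by
multi-start BFGS on the mean squared discrepancy between the observed daily
adherence proportion and the mean predicted probability; evaluation reports
MSE/RMSE/R² with participant-resampling bootstrap CIs and a Ljung-Box
residual test. A self-consistent synthetic-cohort generator (the model run
generatively, plus realistic event logs and drop-out structure) makes the
whole pipeline runnable without any participant data.

## Worked example

Simulate the self-management arm (49 participants × 21 days), apply the
exclusion filter, fit, and evaluate:

```r
library(actradh)

arm  <- simulate_group(group_presets()$self_management, seed = 42)
excl <- exclude_all_zero(arm$cohort)
excl$retention
#> Group self_management: enrolled 49, retained 49 (100% retention), excluded 0

fit <- fit_adherence(excl$cohort, control = fit_control(n_starts = 20, seed = 1))
fit
#> Adherence model fit, group 'self_management' (49 participants x 21 days)
#> Coefficients:
#>   beta0    beta      Tr      U0      R0
#>  1.4072 -0.5648  2.1954 -1.9539 -0.6235
#> Objective (MSE): 0.000566233  RMSE: 0.0238  [20 starts, best #5]

evaluate_fit(fit, B = 1000, lags = 10, seed = 1)
#> Evaluation (value, 90% CI over 1000 bootstrap replicates)
#>   MSE   0.0006 (0.0009 to 0.0027)
#>   RMSE  0.0238 (0.0302 to 0.0521)
#>   R^2   0.5381 (0.1285 to 0.4162)
#>   Ljung-Box (10 lags): Q = 9.4848, p = 0.487
```

Reading the output: the fitted curve tracks the observed group curve to an
RMSE of 0.024 (2.4 percentage points of adherence per day); the recovered
$\beta_0$ and $Tr$ are positive and $\beta$ negative, matching the generating
regime (practice lowers deliberate salience); and the Ljung-Box p-value of
0.49 shows no residual autocorrelation left unexplained. The bootstrap
intervals resample participants under *fixed* coefficients, so they sit
slightly above the in-sample point estimate — they describe sampling
variability of the metric, not refitting variability. The per-day mechanism
split comes from `mechanism_contributions(predict(fit, type = "traces"))`;
here goal pursuit dominates from day 1 (`goal_contrib` ≈ 0.99).

A command-line front end wrapping the same functions lives at
`inst/cli/actradh.R` (subcommands `simulate`, `build-sequences`, `fit`,
`evaluate`, `pipeline`), and `run_pipeline()` executes the full
simulate → exclude → fit → evaluate → decompose chain, writing CSV/JSON
artifacts with the seed and package version embedded.

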
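---
title: "Modelling adherence dynamics of dietary self-monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adherence dynamics of dietary self-monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(actradh)
```

## The behavioural model

Daily self-monitoring of dietary behaviours (SMDB) — photographing or logging
meals in an app — is the workhorse of digital weight-loss interventions, and
adherence to it decays over the weeks of an intervention. `actradh` models the
probability that a participant records their diet on a given day as the outcome
of two competing cognitive routes, using the subsymbolic quantities of the
ACT-R architecture:

* **Goal pursuit.** The SMDB goal is a chunk in declarative memory. Its
  base-level activation is the log-power-law summary of past practice,
  $B(n) = \ln \sum_i t_i^{-d_i}$, where $t_i$ is the age (in days) of the
  $i$-th past execution at prediction day $n$. Total activation is the linear
  form $A = \beta_0 + \beta B$. The goal is retrieved with logistic
  probability $P_G = \sigma\!\big((A - \tau)/s\big)$, and a retrieved
  intention is carried into action with probability
  $P_S = \sigma\!\big((Tr \cdot A - \tau)/s\big)$, where $Tr$ is the
  intention–action transformation coefficient.
* **Habit formation.** The "record diet" production rule accumulates utility
  by the delta rule $U \leftarrow U + \alpha (R - U)$ after every execution,
  starting from $U_0$ with constant per-execution reward $R = R_0$. When the
  goal is *not* retrieved, the rule may still fire habitually against a
  do-nothing rule of utility 0, with Boltzmann probability
  $P_H = \sigma\!\big(U / (\sqrt2\, s_u)\big)$.

The day-ahead success probability is the convex mixture

$$P_{SMDB}(n) = P_G(n)\,P_S(n) + \big(1 - P_G(n)\big)\,P_H(n),$$

and the two summands are the *goal contribution* and *habit contribution*
reported by `mechanism_contributions()`. The predictor is autoregressive: all
quantities on day $n$ are computed from the **observed** 0/1 history on days
$< n$, never from the model's own earlier predictions.

### Spacing-sensitive decay

Each practice decays with its own exponent: $d_1 = a$ and
$d_i = c\,e^{m_{i-1}} + a$, where $m_{i-1}$ is the base-level activation of
the earlier practices evaluated at the moment practice $i$ is encoded. This is
the established two-parameter spacing rule in the ACT-R memory literature:
massed practice (high activation at encoding) is forgotten faster than spaced
practice. A constant-decay mode (`decay_config("constant", d)`) is kept as an
analytically transparent reference; with $c = 0$ the spacing rule reduces to
it exactly, which the test suite asserts bit-for-bit.

### Conventions and degenerate inputs

* Time is whole days; ages are integers $\ge 1$; day indexing is 1-based.
* *Empty history*: before the first observed execution the power-law sum is
  empty and $\ln 0 = -\infty$, so the $\beta B$ term is dropped and
  $A = \beta_0$ — the intercept is the natural prior. `B` is reported as `NA`
  on such days.
* A day is adherent when the event log holds at least `min_entries = 2`
  dietary entries with that calendar date (the study's two-entry rule,
  configurable). Timestamps are taken at face value in a configurable
  timezone; the package does not attempt midnight-spanning heuristics.
* All-zero 21-day sequences carry no temporal signal and are excluded before
  fitting (`exclude_all_zero()`), with retention accounting rounded to the
  nearest percent.

## Parameters

Fixed architecture constants (`system_params()`), with the defaults used
throughout:

| parameter | default | meaning |
|---|---|---|
| `c`, `a` | 0.217, 0.177 | spacing-decay control (dimensionless) |
| `s` | 0.25 | activation noise of the retrieval logistic |
| `s_u` | 0.25 | utility noise of the Boltzmann selection |
| `alpha` | 0.2 | delta-rule learning rate |
| `tau` | 0 | retrieval threshold (activation units) |

These are conventional ACT-R / spacing-model values; the study design this
package emulates fixed its architecture constants from prior modelling work
without printing them, so the defaults here are the package's own choice,
made once, and everything is configurable.

The five free coefficients (`free_params()`) are estimated per intervention
arm: $\beta_0$, $\beta$, $Tr$, $U_0$, $R_0$. None is sign-constrained —
fitted $\beta$ is typically negative (accumulated practice *lowers* the
deliberate salience of the goal, the satiation reading of tailored feedback).
`group_presets()` carries the published coefficient sets of the three arms
(self-management, tailored feedback, intensive support) with their retained
group sizes 49/23/25.

Two genuinely open readings are exposed as switches rather than silently
decided: the intention–action transformation is multiplicative
(`A' = Tr * A`, the default, since a "coefficient" suggests scaling) with an
additive variant (`translation = "additive"`), and the reward schedule is
constant (`R = R0`), with the mixing hook `eps` in the simulator standing in
for unmodelled per-day influences.

## The synthetic cohort generator

No participant-level data are distributed, so `simulate_group()` generates
cohorts with the statistical structure the analysis expects: the model run
*generatively* (each day's outcome drawn from the model's probability given
the simulated history — the generative and inferential models coincide, which
is what makes parameter recovery a meaningful experiment). Around the binary
sequences it emits realistic event logs: 2–4 timestamped entries on adherent
days, at most one on non-adherent days (`p_single_entry`, default 0.2, since
partial single-photo days are common in practice), and a configurable
fraction of forced all-zero drop-outs to exercise the exclusion filter.
Per-participant RNG streams are derived from the master seed by participant
index, so cohorts nest when the group size changes.

What the generator does **not** emulate: between-participant heterogeneity
(every participant in an arm shares one coefficient set, as in the group-level
analysis), weekday/weekend structure, and intervention-content effects. A
passing recovery test therefore shows the estimation machinery is correct
under the stated model — not that the model is correct for any real cohort.

One consequence worth stating plainly: with the default architecture
constants and the tailored-feedback or intensive-support coefficient sets,
the self-consistent forward model equilibrates near ceiling adherence
(group curves ≈ 1.0). A flat, saturated curve contains almost no information
about the coefficients, so sign-level recovery is not attainable for those
arms — recovery guarantees are stated at the level of the predicted curve.
Relatedly, the late-intervention fading of the habit contribution seen when
the model is conditioned on *observed, declining* adherence data does not
reproduce under self-consistent simulation at these constants: sustained
practice keeps $B$ high, $\beta < 0$ pulls $P_G$ down, and the habit share
grows instead. The test suite asserts the pattern as specified and reports
the discrepancy rather than retuning the generator.

## Fitting

`fit_adherence()` estimates the five coefficients per arm by minimizing the
**mean** (not sum) of squared per-day discrepancies between the observed
daily adherence proportion and the mean predicted success probability, all
$T$ days included (day 1 under the empty-history convention). Optimization is
unconstrained BFGS restarted from 20 random initializations
($\beta_0, \beta, U_0 \in [-5,5]$, $Tr, R_0 \in [0,5]$), keeping the
lowest-objective solution; the composite logistic surface is multimodal and
multi-start is the standard remedy. Starts are drawn sequentially from one
seed, so the best objective is non-increasing in `n_starts` and the whole fit
is deterministic given (cohort, seed).

Because the per-practice decays and execution counts depend only on the
observed histories and the fixed constants, they are precomputed once per
cohort; the objective is then closed-form in the coefficients and cheap. The
default gradient is the exact analytic chain-rule gradient; central finite
differences (step $10^{-6}$) remain available as `gradient = "numeric"` and
the two are asserted equal to $10^{-6}$ in the tests. Identical sequences are
collapsed to weighted rows, which matters at high adherence where many
participants share the all-ones history.

Joint identifiability of $(U_0, R_0, Tr)$ from a single 21-point group curve
is doubtful, so the package's recovery experiment (n = 500 per arm, 20
starts) checks that the *fitted predicted curve* matches the generating
model's conditional expected curve (the predicted curve at the true
coefficients on the same cohort) with RMSE < 0.03 — not pointwise coefficient
recovery. The conditional form is preferred over a forward Monte-Carlo
expected curve because it removes the sampling noise of the observed
histories from the comparison.

## Evaluation

`evaluate_fit()` reports MSE, RMSE and $R^2$ (unclipped; negative values are
meaningful) with percentile bootstrap confidence intervals: 1000 replicates
resampling **participants** with replacement at 90% coverage by default,
holding the coefficients fixed at the point estimate (refitting per replicate
is available via `refit = TRUE` but costs three orders of magnitude more).
Residual autocorrelation is tested with the Ljung-Box statistic; the default
of 20 lags on a 21-day series mirrors the degrees of freedom implied by the
reported diagnostics of the study design this package follows, and the
package warns that lags ≈ series length is statistically degenerate —
choose `lags = 10` for a better-behaved test.

## Problem sizes used in the automated experiments

The shipped tests and the acceptance script run: arm cohorts at the study
sizes (49/23/25) and enrolment sizes (66/24/25 with 17/1/0 forced all-zero);
recovery at n = 500 with 20 BFGS starts; Monte-Carlo checks at 800–2000
simulated participants; bootstrap at 1000 replicates. These sizes give
sampling error comfortably below the asserted tolerances while keeping a full
run in tens of seconds.

## Known limitations

* Group-level fitting only; no hierarchical/per-participant coefficients.
* Whole-day resolution; no sub-daily timing effects.
* Spreading activation is absorbed into $\beta_0$ rather than modelled
  against an explicit context.
* The saturation behaviour described above limits what the generator can say
  about the high-adherence arms.
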
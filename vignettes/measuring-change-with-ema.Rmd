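---
title: "Measuring intervention change with EMA versus retrospective questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intervention change with EMA versus retrospective questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intervention trials increasingly measure outcomes two ways at once: a
retrospective questionnaire administered before and after the intervention
(here, trait rumination on a multi-item Likert scale), and an ecological
momentary assessment (EMA) stream — brief in-the-moment prompts delivered
several times a day on a phone, each yielding one bounded rating.  The two
streams rarely agree perfectly, and the disagreement is sharpest when the
quantity of interest is *change*: a person's change score inherits
measurement error from both endpoints, so its reliability is always lower
than the reliability of the levels it is computed from.

`emapsych` implements a four-criterion psychometric evaluation of the two
measurement approaches — reliability (including reliability of change),
convergent validity, sensitivity to change, and incremental criterion
validity — together with a synthetic trial generator with known ground
truth, so every stage of the pipeline can be validated by parameter
recovery rather than by eyeballing.

## The data model

An EMA panel is a long table `(participant, day, beep, value)`.  Days and
beeps are 0-based; measurement time is indexed in fractional days,
`time = day + beep / beeps_per_day`, because the apps' clock times carry no
information the analyses use.  The generating model is a linear growth
curve:

$$y_{ij} = (\gamma_{00} + \gamma_{01} g_i + u_{0i})
         + (\gamma_{10} + \gamma_{11} g_i + u_{1i})\, t_{ij} + e_{ij},$$

with arm indicator $g_i \in \{0,1\}$, person effects
$(u_{0i}, u_{1i}) \sim N(0, \mathrm{T})$ with
$\mathrm{T} = \begin{pmatrix} \tau_{00} & \tau_{01} \\ \tau_{01} & \tau_{11}
\end{pmatrix}$ unstructured, and residuals $e_{ij} \sim N(0, \sigma^2)$
independent given the random effects.  Values are clipped to the scale
bounds *after* noise, so boundary pile-up — a visible feature of real
0–100 slider data — occurs naturally and its effect on estimates can be
studied.

Questionnaire items are congeneric: each of $k$ items is
`loading * latent trait + noise`, rounded and clipped to the Likert range.
With a single loading, the scale's internal consistency is controlled
analytically through the Spearman–Brown relation between single-item
reliability and test length, which is how the generator hits a target
alpha.  The latent trait at the second wave is the baseline trait plus a
true-change component.

Two correlations tie the streams together at the level of *truth*, before
any measurement error:

* `trait_state_cor` — between the latent baseline trait and the person's
  true EMA intercept (default 0.5).  This produces the medium
  single-time-point convergence between questionnaire totals and windowed
  EMA means.
* `change_cor` — between the true trait change and the person's true EMA
  slope (default 0.4).  This is the quantity that observed change-score
  correlations estimate, attenuated by the two change reliabilities.

These two parameters are this package's own extension of the growth model:
without them there would be no ground-truth answer for the convergence
criteria to recover.

Depression is generated on a generic continuous scale at 2 or 4 waves:
baseline plus an improvement component that loads on the true trait change
(`dep_effect_retro`) and the true EMA slope (`dep_effect_ema`) plus noise.
Instrument-specific scoring (CDI, BDI-II, PROMIS) is deliberately not
emulated.

### Missingness

Each scheduled beep is answered independently with probability
`compliance_base − compliance_weekly_decline × week`.  This is missingness
completely at random within week strata — the simplest mechanism
satisfying the missing-at-random assumption that the mixed models rely on.
Real compliance is more structured (time-of-day effects, burst dropout);
passing tests under MCAR therefore validates the estimators' arithmetic
and their behaviour under thinning, not their robustness to informative
missingness.  Defaults (base 0.78, decline 0.03/week for the 21-day
design; 0.84 and 0.034 for the 28-day design) give overall compliance in
the low-to-high 70s and an 80% range respectively, which is typical of
adolescent and adult meditation-app trials.

## Criterion 1: reliability

**Questionnaire.**  Internal consistency is Cronbach's alpha at each wave
(listwise over items, n−1 variances).  The reliability of the residualized
change score is computed from printed-quantity inputs alone:

$$\rho_Z = \frac{\alpha_{T2} + r_{12}^2\,\alpha_{T1} - 2 r_{12}^2}
                {1 - r_{12}^2},$$

where $r_{12}$ is the between-wave correlation.  The orientation is
asymmetric — T2 is the residualized wave — and the comparative statics are
tested as properties: $\rho_Z$ rises with either alpha and falls as
$r_{12}$ grows.  A raw difference-score version is provided for
comparison.

**EMA.**  Each participant's vector of observations is split *at random*
(not odd/even) into two halves differing in size by at most one; the
statistic of interest — the mean, or the OLS slope of value on fractional
day — is computed in each half and the two half-statistics are correlated
across participants.  Because each half uses half the data, the raw
correlation underestimates full-length reliability, so the Spearman–Brown
double-length adjustment $2r/(1+r)$ is reported alongside it.  A single
random split is noisy; `n_splits` averages the raw correlation over
independent seeded splits before adjustment.  The default remains one
seeded split, matching common practice; every split seed is recorded in
the estimate.

The multilevel alternative estimates slope reliability inside the mixed
model: for participant $j$ with centered time sum of squares $SS_{t,j}$,

$$\lambda_j = \frac{\tau_{11}}{\tau_{11} + \sigma^2 / SS_{t,j}},$$

and the reported value is $\bar\lambda$.  Variance components come from
the maximum-likelihood fit (REML by flag).  The closed-form design
expectation of the same quantity, `expected_slope_reliability()`, is the
oracle for validation: under full compliance it enumerates the scheduled
grid exactly; under partial compliance $p$ it uses the simple-random-sample
approximation $E[SS_t] = (pN - 1)\,\mathrm{Var}(t)$ over the grid.  The
approximation ignores the nonlinearity of $\lambda$ in $SS_t$ and the
week-structure of the thinning; at the compliance levels simulated here it
agrees with brute-force enumeration to well inside the ±0.03 tolerance the
validation tests use.

Validation conditions for these oracle comparisons use generating
parameters with negligible scale censoring (under 1% of observations at a
bound).  Clipping attenuates both $\tau_{11}$ and $\sigma^2$ relative to
their generating values, so an oracle computed from *generating*
parameters is only valid where the linear-Gaussian model actually holds;
heavy-censoring behaviour is a property of the data, not an estimator
defect, and can be explored by raising `sigma2` or moving `gamma00`
toward a bound.

## Criterion 2: convergence

Single-time-point convergence correlates the T1 questionnaire total with
mean EMA over the first `k` days and the T2 total with mean EMA over the
last `k` days (`k = 3` by default; windows are half-open in 0-based days,
`[0, k)` and `[D−k, D)`).  Change-score convergence correlates the
residualized questionnaire change with the person-level OLS slope
(minimum 4 observations, configurable to reproduce harsher filters such
as ≥40 time points).  The central property, tested by Monte Carlo, is
attenuation:

$$r_{\text{observed}} \approx \rho \sqrt{\rho_{Z}\,\lambda},$$

the true change correlation shrunk by the geometric mean of the two change
reliabilities.  This is why change-score correlations sit far below
single-time-point correlations even when the underlying constructs are
substantially related.

## Criterion 3: sensitivity to change

For two-arm designs the questionnaire effect is the ANCOVA-style
regression of T2 on T1 plus group; the EMA effect is the group × time
interaction from the random-slope mixed model.  Both are standardized as
growth-model effect sizes: $d = \beta_{\text{time}} \times D / SD_{raw}$,
the model-implied change over the whole trial of duration $D$ days in
baseline raw-SD units.  The "× duration" reading of the growth-model
convention is explicit in the function signature so that per-week or
per-day alternatives are one call away.  For single-arm designs the
pipeline reports the paired pre/post questionnaire effect and the EMA time
effect instead, flagging the group comparison as skipped.

The standardizer for ANCOVA and paired effects defaults to the baseline
raw SD, consistent with the growth-model convention's denominator; pooled
and difference-score SDs are selectable.  For the EMA stream the baseline
SD is the SD of day-0 observations.

## Criterion 4: incremental criterion validity

With four depression waves, a mixed model over the repeated outcome with
time centered at the final follow-up, baseline depression as covariate,
participant random intercepts and slopes, and *both* change × time
interactions entered simultaneously — so each coefficient is the
prediction added beyond the other measure.  Time centering is
configurable; re-centering changes main effects but not the interaction
slopes, which is tested as an invariance.  Because baseline depression
appears both as the first outcome wave and as the covariate in the source
design, the default here drops wave 0 from the outcome vector when the
covariate is present (`include_baseline_wave` restores it); neither
variant is canonical and both are available.

With only two waves, OLS of post-test depression on pre-test depression
plus both change scores, with a condition-number warning for
near-collinear predictors.

## Robustness and numerical choices

* **Robustness strategy.**  Outlier handling offers (a) standard ML
  mixed models on winsorized inputs — the default, matching the explicit
  winsorization step of the analysis plan — and (b) an iterative Huber
  reweighting of residuals (k = 1.345, MAD scale, ≤10 iterations).  The
  choice is recorded on every fit.  M-estimation with a dedicated robust
  mixed-model estimator is a different procedure and exact parity with it
  is not claimed.
* **Winsorization** defaults to the 5th/95th percentile pair using type-7
  (linear-interpolation) quantiles, fixed for bit-reproducibility.  It is
  a single-pass transform: re-applying with the same numeric bounds is a
  no-op.  By default derived change scores and model inputs are
  winsorized, not raw EMA observations (a flag exposes the latter), since
  the bounded momentary scale already limits the influence of any single
  beep.
* **Estimation** is ML rather than REML by default so that variance
  components match the likelihood used for missing-data handling;
  a REML flag is available everywhere.  p-values use the Wald normal
  approximation — adequate for panels with hundreds of participants and
  thousands of observations, and noted as approximate for small samples.
* **Degenerate inputs** error early and name the problem: zero T1
  variance for residualized change, a single distinct day for a slope,
  zero variance in a split half (naming the half), compliance schedules
  that cross zero (naming the week), fewer than 3 eligible participants
  for a split-half correlation.
* **Correlations** are Pearson throughout, matching the OLS context of
  the statistics being correlated; listwise deletion for correlation and
  regression analyses, all available observations for mixed models.
* **Weekly compliance trend** regresses participant-week completion
  proportions on 0-based week index with a participant random intercept
  (pooled OLS by flag); the coefficient is in completion-proportion
  points per week.

## Validation problem sizes

The test suite validates the estimators at sizes chosen to make
Monte-Carlo error small relative to the assertion tolerances: the
split-half and multilevel reliability estimates against the closed-form
oracle on a 2,000-participant trial (tolerance ±0.03); arm-effect
recovery over 200 simulated 50-participant trials (within 3 Monte-Carlo
SEs); attenuation over 30 replications of a 300-participant trial
(tolerance ±0.05); criterion-validity coverage and sign recovery over 100
replications each at 150 participants.  The demonstration configurations
shipped with the package are a 320-participant two-arm 21 × 3 trial and a
92-participant single-arm 28 × 4 trial, mirroring the designs described
above.

## Limitations

The generator emulates the measurement structure of app-based
mindfulness trials, not their content: no adaptive intervention delivery,
no time-of-day or context effects, no autocorrelated within-day dynamics,
no informative missingness, and a linear true trajectory.  Passing
recovery tests under this model shows the estimators are correct under
their stated assumptions; it does not show those assumptions hold in any
particular real trial.  Generalizability-theory decomposition with a
second momentary item, empirical-Bayes slope estimates (avoided because
shrinkage biases downstream regressions), and lagged mediation analyses
are out of scope.
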
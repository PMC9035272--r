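---
title: "Two-stage hurdle modeling of skewed length of stay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hurdle modeling of skewed length of stay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In-hospital length of stay (LOS) after elective surgery is a continuous,
non-negative outcome with extreme right skew: roughly 90% of encounters
resolve within a week, while a small minority stretch to weeks or months.
A single regression model trained on such data faces an unattractive
trade-off. Squared-error training is dominated by the rare tail; robust or
transformed fits do better on the majority but systematically under-predict
long stays — and pre-operative covariates carry little information about
the complications that drive those long stays in the first place.

`loshurdle` implements a two-stage (hurdle) treatment of this problem:

1. **Stage 1 (gate).** A binary classifier estimates the probability that
   an encounter becomes *prolonged*, defined as `los >= tau_c` (default
   `tau_c = 7` days). A probability cutoff is tuned on out-of-fold
   predictions so that short-class sensitivity meets a target (default
   0.99): almost all truly short stays must pass the gate and receive a
   numeric prediction.
2. **Stage 2 (regressor).** Among gate-passing encounters, a regressor
   trained only on encounters with `los <= tau_r` (default 35 days)
   predicts the actual LOS, by default on the natural-log scale and
   back-transformed to days. Setting `tau_r` above `tau_c` deliberately
   exposes the regressor to stays beyond the gate threshold so that its
   predictions are not artificially capped at `tau_c`, while excluding the
   extreme tail entirely.

Encounters flagged by the gate receive a "prolonged" label and *no*
numeric estimate. This is the model's explicit admission that it cannot
resolve the tail, rather than a confidently wrong number.

## Evaluation losses

For aligned observed/predicted vectors \(y_i, \hat y_i\) the package
provides the standard mean squared error, mean absolute error (days), and
mean relative error \(\frac1n\sum_i |\hat y_i - y_i|/y_i\), each overall
and stratified by the observed-outcome bins 0–2, 2–4, 4–7 and ≥ 7 days
(half-open intervals, so each encounter lands in exactly one bin).

The hurdle model as a whole is scored by a truncated hinge loss: per
encounter,

\[
\ell_i = \begin{cases}
0 & y_i \ge \tau_c \text{ and } \hat y_i \ge \tau_c\\
|\hat y_i - \tau_c| & y_i \ge \tau_c \text{ and } \hat y_i < \tau_c\\
|\hat y_i - y_i| & \text{otherwise.}
\end{cases}
\]

Both truth and prediction beyond the threshold costs nothing (the tail is
declared out of scope); a missed prolonged stay is penalized only up to
the threshold; all other encounters pay ordinary absolute error. The loss
is pointwise bounded by the MAE and converges to it as
\(\tau_c \to \infty\).

Gated encounters have no numeric prediction, so to score them with any
day-scale loss the package imputes \(\hat y_i = \tau_c\)
(`impute_gated()`): a truly prolonged gated encounter contributes zero
truncated-hinge loss, a falsely gated short one contributes
\(|\tau_c - y_i|\). This is the only convention under which the hinge
rule is computable for gated rows; it is a package convention, stated
wherever results are reported, not an established community standard.

## Decision-rule conventions

* **Prolonged class:** `los >= tau_c` (the boundary has probability ~0
  for continuous LOS, but the `>=` convention is applied consistently in
  labels, losses and sensitivity).
* **Cutoff tuning** (`tune_cutoff()`): candidates are the distinct
  out-of-fold score values plus an "everyone short" rule above the
  maximum score. Among cutoffs whose short-class sensitivity meets the
  target, the one maximizing prolonged-class sensitivity is chosen; both
  sensitivities are monotone in the cutoff, so this is the smallest
  admissible cutoff, and ties resolve toward it. An alternative mode
  constrains prolonged-class sensitivity instead, for operating points
  specified from the tail side. Scores must come from out-of-fold
  predictions — in-fold scores would leak the training fit into the
  operating point.
* **Calibration slope** (`calibration_slope()`): the least-squares slope
  of observed on predicted, \(\mathrm{cov}(y,\hat y)/\mathrm{var}(\hat y)\),
  computed over numerically predicted encounters only. Slope 1 is perfect;
  below 1 means large outcomes are under-predicted. The direction of the
  regression (observed on predicted) is chosen so that this reading holds.

## Base learners

Three algorithm families sit behind one contract (`learner_spec()`,
`fit_learner()`): a LASSO-penalized linear model (glmnet), a random
forest (ranger), and a single-hidden-layer feed-forward network (nnet),
each for both regression and binary classification. Categorical features
are one-hot encoded against an explicit reference level; missing numeric
values are imputed with the training median plus a missing-indicator
column; the network additionally standardizes numeric inputs.

Hyperparameters not pinned by the user are chosen by internal fivefold
cross-validation over small grids: the glmnet lambda path; forest `mtry`
over \(\{\lfloor\sqrt p\rfloor, \lfloor p/3\rfloor\}\) with 300 trees and
minimum node size 5; network width \(\{3, 8\}\) and weight decay
\(\{0.01, 0.1\}\). The grids are deliberately small — the point of the
package is the two-stage structure and its evaluation, not exhaustive
tuning — and every grid choice is overridable through
`learner_spec(hyperparameters = ...)`, which pins values and skips the
search. Fits are reproducible from the spec seed; the network is
reproducible up to floating-point tolerance.

A property worth knowing: forest predictions are averages of training
outcomes, so they can never exceed the training maximum. A one-stage
forest trained on outcomes truncated at 7 days therefore *never* predicts
a prolonged stay — truncation buys robustness at the price of total tail
blindness. The same mechanism is why raising `tau_r` extends the
reachable prediction range of the stage-2 forest.

## The synthetic cohort generator

No patient-level data ship with the package. `generate_cohort()` draws
cohorts with the structure the method assumes, so every pipeline component
is testable from a seed alone:

* **Covariates** mirror a typical elective-surgery descriptive table:
  age (mean 58, SD 19 years), sex (52% female), race (72% / 20% /
  2.5% / 5.5% NHW/NHB/Hispanic/Other), smoking (34% ever), BMI category
  (4.5% / 22% / 30.5% / 43% under/normal/over/obese), and three
  overdispersed utilization counts (hospital, ambulatory, emergency
  encounters).
* **Prolonged risk** is logistic in centered covariate terms. The
  intercept is solved numerically for each draw so that the configured
  prevalence (default 0.099) is the exact mixture target for the sampled
  covariates; the default coefficients give a latent risk score with
  oracle discrimination around AUC 0.8 and average precision 0.4 —
  informative, far from deterministic, as pre-surgical covariates are.
* **Short stays** are log-normal (SD 0.8 on the log scale) with small
  covariate shifts, truncated to `[0.25, 7)` days; the location is solved
  so the short-branch median equals its target (default 2.3 days).
  Fractional days are allowed; the 0.25-day floor reflects that same-day
  discharges still occupy a fraction of a day.
* **Prolonged stays** are 7 days plus a generalized-Pareto draw
  (shape 0.35, scale 6): median around 12 days, admissible draws into the
  hundreds of days — and *independent of the covariates*. Conditional on
  being prolonged, duration is pure noise. This is the regime the hurdle
  design targets, and the regime in which its superiority over a single
  regressor is testable.
* **`separable_mode`** adds a binary `high_risk` feature that *equals*
  the prolonged indicator, making the gate perfectly learnable — used for
  pipeline tests with a known answer.

What the generator does **not** emulate: procedure codes, medications,
comorbidity profiles, temporal drift, or any dependence of tail duration
on covariates. Tests passing on these cohorts demonstrate that the
machinery is correct and that the hurdle structure helps *when its
assumptions hold*; they say nothing about performance on any real EHR
extract.

## Study-design harness

`split_data()` makes the canonical 2/3 train, 1/3 test partition.
`crossval_compare()` runs the analytic grid (approach × algorithm ×
transform) with one shared fivefold partition, scoring pooled out-of-fold
predictions on the day scale; pooling (rather than averaging per-fold
losses) is the default because losses are means of per-sample terms, and
a config switch is unnecessary — a failing cell is recorded with its
error message and the run continues. Rows are put in a canonical sort
order before fold assignment so results do not depend on row order.
Test-set metrics from `evaluate_model()` carry percentile bootstrap
intervals (default B = 1000) obtained by resampling test rows with the
model held fixed — the uncertainty quantified is sampling error of the
final estimate, not refitting variability. Resamples on which a metric is
undefined are redrawn and counted. The percentile method is used rather
than BCa: simplest method consistent with row-resampling of a final
estimate.

## Numerical choices and degenerate inputs

* Losses on empty vectors, relative error at `y = 0`, calibration on
  constant predictions, sensitivity with no truly short encounter, and
  PR/ROC with one class all raise informative errors rather than
  returning silent NA or 0; an empty outcome bin reports `NA` with
  `n = 0`, never a zero loss.
* Cutoff candidates include a rule above the maximum score; when even
  that is the only admissible rule and the maximum score is 1, tuning
  errors with the best attainable sensitivity rather than inventing an
  out-of-range cutoff.
* AP uses the step-wise sum \( \sum_k (R_k - R_{k-1}) P_k \) over
  descending thresholds with ties grouped; AUC uses the rank
  (Mann–Whitney) statistic with half credit for ties. Both are computed
  with cumulative sums in \(O(n\log n)\) and verified in tests against
  exhaustive enumeration.
* Day-scale predictions are floored at 0 (a negative LOS estimate from a
  linear model on the identity scale is meaningless).
* All derived seeds stay below \(2^{31}\); fold assignment and simulation
  restore the caller's RNG state.

## Problem sizes used in the checks

The bundled tests and the acceptance script exercise the pipeline at
cohort sizes of 400–12,000 encounters with forests of 50–300 trees —
sizes chosen so the full statistical behaviour (prevalence calibration,
cutoff transfer within binomial error, hurdle-versus-one-stage ordering
over 20 replicates) is visible while a complete run stays in the range of
a coffee break. All thresholds in those checks are stated in terms of
sampling error under the generator's own parameters, not tuned to any
particular draw.

## Known limitations

* The customized-loss imputation for gated encounters (`tau_c`) is a
  convention; alternatives (excluding gated rows, imputing a tail mean)
  would change reported MAE-style numbers.
* Stage-1 and stage-2 are fit independently; no uncertainty flows from
  the gate into the regressor.
* The comparison grid refits hyperparameters inside each fold from the
  same small grids; with very small folds the selected values can be
  unstable (pin hyperparameters for strict comparability).
* The generator's tail is covariate-independent by design. If, in real
  data, prolonged durations are partly predictable, a one-stage model
  may close part of the gap the hurdle enjoys here.

## A minimal session

```{r, eval = FALSE}
library(loshurdle)

cohort <- generate_cohort(cohort_spec(n = 12000, seed = 1))
parts <- split_data(cohort, split_spec(seed = 1))

config <- two_stage_config() # tau_c 7, tau_r 35, RF + log stage 2
model <- fit_two_stage(parts$train, los, config)
glance(model)

report <- evaluate_model(model, parts$test, los, seed = 1)
dplyr::filter(report, bin == "overall")
autoplot(attr(report, "curves"))
```
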
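---
title: "Survival estimation by period-replicated classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival estimation by period-replicated classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casesurv)
```

## The problem

Registry-scale time-to-event data — transplant outcomes, device failures,
customer churn — are dominated by censored records: for most subjects we only
know that the event had not happened by their last follow-up. Classical tools
summarise such data with population curves (Kaplan–Meier) or
proportional-hazards adjustments of a shared baseline (Cox), both of which
force every subject onto essentially the same curve shape and struggle with
long horizons, where the subjects with known long-term outcomes are a tiny,
heavily imbalanced minority.

`casesurv` takes the discrete-time route: the survival problem is rewritten as
a binary classification problem on person-period data, a classifier supplies
period-specific survival scores, and a calibration step turns those scores
into individual survival curves from which exact survival times can be
estimated.

## The augmentation operator

A dataset holds one record per subject: covariates $x_i$, an observed time
$t_i \ge 0$ in period units, and an event indicator $\delta_i \in \{0, 1\}$.
Given a horizon of $P$ periods, each record is replicated into labelled
person-period rows $(x_i, \tau, y_{i\tau})$:

* **event records** ($\delta_i = 1$) contribute exactly $P$ rows,
  $\tau = 1..P$, with $y_{i\tau} = 1$ for
  $\tau \le \min(\lfloor t_i \rfloor, P)$ and $0$ afterwards;
* **censored records** ($\delta_i = 0$) contribute
  $\min(P, \lfloor t_i \rfloor)$ rows, all positive — nothing is asserted
  beyond the observed follow-up.

Two boundary conventions deserve a note. First, times are reduced to
*completed periods* via $\lfloor t \rfloor$: a subject censored at 6.4 years
has verifiably survived 6 whole years. Second, the label rule is
$y_{i\tau} = 1 \iff \tau \le \lfloor t_i \rfloor$ for events and censored
records alike. A strict inequality for censored records would drop the last
observed period of every censored subject; the closed rule is the one
consistent with treating $\lfloor t \rfloor$ as fully observed periods, and
is the convention this package follows throughout (the ideal step function in
the evaluation metric is closed at the event time for the same reason).

The positive-class ratio of the augmented table has the closed form
$$\frac{\sum_i \min(\lfloor t_i \rfloor, P)}
       {\sum_{\delta_i=1} P + \sum_{\delta_i=0} \min(\lfloor t_i \rfloor, P)},$$
implemented in `case_class_ratio()` and verified in the tests against a
brute-force count over the augmented rows.

One property of this formula is worth stating because it is easy to get
backwards: the positive ratio is **non-increasing in $P$** for any dataset.
Censored records contribute only positive rows (per-record ratio 1), event
records contribute a fraction $\min(\lfloor t \rfloor, P)/P$ that falls as
$P$ grows, and the event rows' weight in the total grows proportionally to
$P$. "Lengthening the horizon improves balance" is therefore a statement
about censoring-dominated data, where the all-positive censored rows make the
positive class the majority and a longer horizon pulls the ratio *down*
toward one half. `imbalance_scenario()` builds generator configurations for
the two regimes and the test suite demonstrates both behaviours.

## Classification and calibration

A binary classifier (gradient-boosted trees by default, a probability forest
as the alternative; both run single-threaded with a fixed seed so results are
reproducible) is fitted on the augmented rows with the period index included
as an ordinary feature. At prediction time every subject is expanded over all
$P$ periods and scored, giving a raw survival profile.

Raw classifier scores are not calibrated probabilities, so they pass through
**adjusted Bayesian binning-in-quantiles** (`fit_abbq()`): scores are sorted
into $M$ quantile bins of near-equal occupancy, each bin records its
empirical survival fraction $\hat p_{\mathrm{emp},m}$ and score range, and a
score $p$ in bin $m$ maps to
$$\hat p = \hat p_{\mathrm{emp},m} + \frac{1}{M}\cdot
  \frac{p - \min_m}{\max_m - \min_m}.$$
The second term is an intra-bin adjustment that preserves the ranking of
scores within a bin instead of flattening them to a single value. Numerical
choices: the additive form can exceed 1, so outputs are clipped to $[0,1]$
(re-normalisation was rejected as it would distort the bin mean); a
degenerate bin with zero score spread uses $1/2$ as its normalised position;
scores outside the fitted range are clamped into the first or last bin. An
optional `centered` mode subtracts $0.5/M$ so the adjustment is mean-zero;
it is off by default because the additive form is the canonical one. The bin
count is a tunable hyperparameter: `tune_bin_count()` does an exhaustive grid
search minimising expected calibration error on a disjoint validation split,
with ties broken toward fewer bins (a deterministic replacement for
black-box optimisation over the same candidate space; the optimisation
target had to be chosen, and ECE is the natural calibration criterion).
Calibration is fitted once on pooled all-period scores; a per-period variant
would need far more calibration data per fit and is out of scope.

## Individual curves and survival-time estimation

The calibrated per-period probabilities *are* the individual survival curve:
$S_i(\tau) = \hat p_{i\tau}$, $\tau = 1..P$, linearly interpolated between
integer periods with the convention $S_i(0) = 1$ (everyone is alive at the
origin; the first segment therefore falls from 1 to $S_i(1)$). Curves are
deliberately **not** forced to be monotone: period-specific classification
can express non-monotone risk — e.g. a cohort whose long-term survivors
plateau — which is precisely what population product-limit curves cannot.
Times beyond $P$ are a range error rather than an extrapolation.

Three estimators turn a curve into an exact survival time:

* **threshold** — the last period with $S_i(\tau) > \theta$ (default
  $\theta = 0.5$); 0 if no period qualifies, $P$ if all do;
* **gradient** — the period on which the steepest one-period drop lands,
  ties toward the earliest, $P$ for a never-decreasing curve; discrete first
  differences are used without smoothing, since the curve is discrete to
  begin with;
* **regression** — a regressor fitted on the original covariates plus the
  $P$ probability columns (`attach_survival_features()`), trained on event
  subjects only, because only they have an observed survival time. The
  default family is a seeded gradient-boosted regressor; any fit/predict
  pair satisfying the same contract can be substituted. Predictions are not
  clipped — the events-only training targets already live in the observed
  range.

Accuracy is summarised as the fraction of event subjects predicted within a
window. A "five-year window" is ambiguous between a total width of five
years ($|\hat T - T| \le 2.5$) and a five-year margin on either side;
`windowed_accuracy()` defaults to the stricter total-width reading and
exposes the other as `mode = "full"`.

## Temporal-stratified cross-validation

Plain stratified $k$-fold balances the label but ignores the period
structure, so individual folds can over-represent early or late periods.
`tsk_fold()` stratifies jointly on (period, label): rows are shuffled within
each stratum under a seed and dealt round-robin, so within every stratum the
fold sizes differ by at most one and each fold preserves the per-period
class balance. Strata smaller than $k$ only warn. The default row-level
split reproduces the method as introduced — note that a subject's replicates
can then land in both training and test folds, an optimistic-leakage path;
`grouped = TRUE` assigns whole subjects (stratified by completed periods and
event status) and removes it. Both modes are exposed because the published
protocol is row-level while the grouped split is the defensible one for
honest generalisation claims. Period strata can be widened via
`interval_width` when events are sparse.

## Curve evaluation: iAUSC and mAUSC

The ideal prediction for a subject with event time $T_i$ is the step
function $1[t \le T_i]$; its continuous relaxation is a *decreasing* sigmoid
$S(t) = 1/(1 + e^{M_s (t - T_i)})$ passing through $0.5$ at $T_i$ (the sign
is chosen so the curve decreases — an increasing "ideal survival curve"
would be meaningless). A predicted curve is scored by its time-weighted mean
absolute deviation from the step,
$$E_i = \frac{\int_0^P |\hat S(t) - 1[t \le T_i]|\, w(t)\, dt}
             {\int_0^P w(t)\, dt}, \qquad
  w(t) = e^{-|t - \min(T_i, P)|/P},$$
reported as the score $\mathrm{iAUSC}_i = 1 - E_i$ so that **higher is
better**: a perfect step predictor scores 1 and the uninformative constant
$\hat S \equiv 0.5$ scores exactly 0.5 regardless of the weights. The raw
weighted error is kept as an attribute for anyone who prefers the error
orientation. The weight concentrates accuracy demands near the true event
time and decays to $e^{-1}$ at distance $P$; event times beyond the horizon
are capped at $P$ inside the weight.

Integration is trapezoidal with a configurable step (default 0.01 periods),
with the two sides of the step discontinuity integrated separately so the
jump never falls inside a trapezoid; halving the step moves smooth-curve
scores by less than $10^{-4}$. `mausc()` averages iAUSC over event subjects
only — censored subjects have no observed $T_i$, so no censoring-distribution
weighting is needed, at the cost of the metric saying nothing about
censored-subject curves (a real limitation on low-event data).

## Temporal variable importance

For each period $\tau$, exact tree-path SHAP attributions are computed for
the rows $(x_i, \tau)$ of the subjects *observed* to survive $\tau$ periods
($I_\tau = \{i : \lfloor t_i \rfloor \ge \tau\}$ — observed survivors, not
model-predicted ones), and averaged into a feature-by-period profile
$\bar\varphi_{j,\tau}$; per-subject trajectories are retained so individual
deviations from the population trend can be inspected. Attributions are on
the classifier's margin (log-odds) scale. The period feature's own
attribution is computed but reported separately, since it reflects the time
axis rather than a covariate. Cohorts larger than a configurable cap
(default 2,000 subjects) are subsampled under a seed to keep the cost
linear.

One practical caveat the test suite encodes: survivor-set attribution means
are only interpretable **out-of-sample**. On the training cohort itself, a
flexible classifier partially memorises its rows, which inflates the
predictions of training survivors and drags every feature's survivor-mean
attribution upward — including pure-noise features. Profiles should be
computed on subjects the model was not fitted on; the fixtures fit on one
half of a cohort and attribute on the other.

## The synthetic-data generator

`generate_survival_data()` draws standard-normal covariates and samples a
discrete-time mechanism with logistic per-period hazards
$h_i(\tau) = \mathrm{logit}^{-1}(\alpha_\tau + \sum_j \beta_{j,\tau}
x_{ij})$, supporting time-varying effects ($\beta_{j,\tau}$ as an
$F \times$ periods matrix), administrative entry-time censoring (follow-up
drawn uniformly from a window, mimicking "enrolled $x$ years before the data
freeze"), optional random dropout, and a returned ground truth
($S_i(\tau) = \prod_{u \le \tau}(1 - h_i(u))$ and the true event time) for
recovery tests.

A subject who fails the period-$\tau$ hazard draw dies *partway through*
that period: the continuous event time lies in $(\tau - 1, \tau)$, so the
completed periods $\lfloor t \rfloor$ equal the periods actually survived
and the augmented label's population target $P(y_\tau = 1 \mid x)$ coincides
exactly with the true $S(\tau \mid x)$. (With integer event times the label
convention — a death at $t = 6$ still counts period 6 as survived — would
make the classifier target $S(\tau - 1)$, a one-period upward bias against
any ground truth.)

What the generator emulates: covariate-dependent hazards, time-varying
effects, entry-time censoring, long-horizon class imbalance, and — via a
bimodal baseline — non-monotone survival-time densities with a late bump.
What it does not: time-varying covariates within a subject (the method
copies the baseline feature vector to every period), informative censoring,
missing data, correlated or categorical covariate structure, and the sheer
width of real registries. Passing recovery tests on this generator shows the
machinery is correct under the method's own assumptions; it does not certify
performance on data that violate them.

Default scales used by the test suite and the reproduction script, chosen as
a realistic desk-scale register: cohorts of 400–2,400 subjects, horizons of
8–10 periods, baseline log-odds around $-2.2$ (per-period hazard
$\approx 10\%$), unit-scale effects, and follow-up windows of 1–2 horizons.
The curve-recovery and estimator-ordering scenarios use follow-up of at
least the horizon, mirroring a registry eligibility rule of a minimum
follow-up; with administrative censoring *inside* the horizon the
person-period target is upward-biased by construction (censored subjects
appear only while alive, all-positive), which is a property of the method
itself, not of this implementation.

## A short worked run

```{r pipeline, eval = FALSE}
gen <- generate_survival_data(
  synth_config(n = 2000, n_features = 3, horizon = 10, baseline = -2.2,
               effects = 0.8, followup_min = 10, followup_max = 20),
  seed = 1)
run <- run_case_pipeline(gen$data, horizon = 10, seed = 1)
run
```

`run_case_pipeline()` splits subjects into fit / calibration / test parts,
fits the classifier on the fit part, tunes and fits the calibration map on
the held-out calibration scores, and evaluates curves, time estimates, ECE
and mAUSC on the test part, so no quantity is scored on rows used to fit the
stage producing it (up to the row-level fold caveat above, which the
pipeline avoids by splitting subjects, not rows).
`evaluate_against_baselines()` adds Cox and random-survival-forest
comparators through the standard `survival` and `ranger` machinery — those
models are wrapped, not reimplemented, and the comparison harness reports
C-index and mAUSC for each (an integrated Brier score wrapper is omitted:
no suitable established implementation is available among this package's
dependencies, and reimplementing one is out of scope).

## Known limitations

* mAUSC evaluates event subjects only; on heavily censored data it measures
  a minority of the cohort.
* The row-level cross-validation mode shares subjects between folds by
  design fidelity; use `grouped = TRUE` for honest generalisation estimates.
* Calibration is pooled across periods; per-period miscalibration patterns
  are averaged out.
* Importance profiles require the boosted-tree backend (exact tree-path
  attributions); the forest backend has no attribution path here.
* With censoring inside the horizon, period-level survival scores are
  biased upward relative to the true survival function (survivor-only
  censored rows); interpret curves accordingly or restrict to cohorts with
  follow-up beyond the horizon.
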
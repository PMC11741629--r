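# casesurv

Individualized survival curves and exact survival-time prediction by
**period-replicated classification**, for censored time-to-event data at
long horizons — the setting (transplant registries, device reliability,
churn) where population Kaplan–Meier curves and proportional-hazards models
flatten individual differences and the subjects with known long-term
outcomes are a small, imbalanced minority.

## What it does

Given records $(x_i, t_i, \delta_i)$ — covariates, observed time in periods,
event indicator — and a horizon of $P$ periods:

1. **Augment.** Each record becomes person-period rows $(x_i, \tau,
   y_{i\tau})$: an event record yields $P$ rows with $y = 1$ up to
   $\min(\lfloor t_i\rfloor, P)$ and $0$ after; a censored record yields
   $\min(P, \lfloor t_i\rfloor)$ all-positive rows. The positive-class
   ratio has the closed form
   $\sum_i \min(\lfloor t_i\rfloor,P) \,/\, |D_{\text{aug}}|$.
2. **Classify.** A seeded tree-ensemble classifier (xgboost or ranger) is
   fitted on the augmented rows with the period as a feature.
3. **Calibrate.** Raw scores pass through adjusted Bayesian
   binning-in-quantiles: per quantile bin $m$,
   $\hat p = \hat p_{\text{emp},m} + \tfrac1M (p-\min_m)/(\max_m-\min_m)$,
   clipped to $[0,1]$; the bin count $M$ is tuned by validation expected
   calibration error.
4. **Curves.** The calibrated per-period probabilities are the individual
   survival curve $S_i(\tau)$, linearly interpolated with $S_i(0)=1$, and
   deliberately not forced monotone.
5. **Estimate survival times** by threshold ($\max\{\tau: S_i(\tau) >
   \theta\}$), steepest one-period drop, or a regressor trained on
   covariates + the $P$ probability columns (events only).
6. **Validate and evaluate** with temporal-stratified k-fold (joint
   (period, label) strata), the time-weighted curve score
   $\text{iAUSC} = 1 - \int |\hat S - 1[t\le T_i]| w \,dt / \int w\,dt$
   with $w(t)=e^{-|t-T_i|/P}$ (its event-set mean is mAUSC), expected
   calibration error, and per-period SHAP importance profiles
   $\bar\varphi_{j,\tau}$ over observed survivors.

A seeded synthetic-data generator with logistic discrete-time hazards,
time-varying effects, administrative censoring and known ground truth
backs the test suite and the reproduction script.

## Worked example

```r
library(casesurv)
gen <- generate_survival_data(
  synth_config(n = 300, n_features = 4, horizon = 8), seed = 3)
run <- run_case_pipeline(gen$data, horizon = 8, seed = 3)
run
```

```
case_run (horizon 8, seed 3)
  augmented class ratio : 0.5594
  ECE  raw -> calibrated: 0.1536 -> 0.0706 (M = 20 bins)
  mAUSC  CASE / KM      : 0.6456 / 0.5214
  windowed accuracy     : threshold 0.583 | gradient 0.500 | regression 0.639
```

Reading it: augmentation turned 300 subjects into person-period rows that
are 56% positive; calibration halved the expected calibration error on the
held-out test rows using 20 quantile bins; the individual curves score
mAUSC 0.65 against 0.52 for the single Kaplan–Meier population curve
(0.5 is the uninformative-constant score); and the regression estimator
predicts the most test-set event times within a five-year window (total
width, i.e. ±2.5 periods). `run$curves` holds the per-subject curves,
`run$estimates` the per-method survival times, and
`evaluate_against_baselines()` adds Cox and random-survival-forest
comparators via the `survival` and `ranger` packages.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/case.R simulate --n 2000 --horizon 10 --seed 1 --output data.csv
Rscript inst/cli/case.R augment  --input data.csv --horizon 10 --output dcase.csv
Rscript inst/cli/case.R run      --input data.csv --horizon 10 --seed 1 --outdir out/
```

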
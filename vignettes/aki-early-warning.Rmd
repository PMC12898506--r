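---
title: "Dynamic 24-hour AKI early warning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic 24-hour AKI early warning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`akiews` builds a dynamic early-warning score for incident acute kidney
injury (AKI) in the ICU: every 6 hours during a stay it asks whether AKI, by
KDIGO criteria, will begin within the next 24 hours. This vignette explains
the model and its assumptions, the tunable parameters and why their defaults
are what they are, the synthetic cohort generator and what passing tests on
it do and do not establish, and the numerical and design decisions made
where the problem was genuinely open.

## 1. Outcome definition: time-respecting KDIGO staging

AKI is staged from three evidence streams, evaluated at every serum
creatinine (SCr) timestamp, every whole hour, and every renal replacement
therapy (RRT) start:

* **Creatinine.** At time `t` the current SCr is compared against two
  time-varying baselines computed from *strictly prior* measurements: the
  minimum over `(t − 48 h, t)` for the absolute-rise criterion
  (rise ≥ 0.3 mg/dL → stage 1) and the minimum over `(t − 168 h, t)` for
  the relative-rise criteria. Ratio bands are half-open — `[1.5, 2) → 1`,
  `[2, 3) → 2`, `[3, ∞) → 3` — matching KDIGO-2012's 1.5×/2×/3× wording.
  When no prior SCr exists in a lookback the criterion is not computable.
* **Urine output (UO).** Charted volumes are summed over the half-open
  windows `[t − W, t)` for `W ∈ {6, 12, 24}` h and normalized by `W` times
  the most recent body weight. Stage 1 if the 6 h rate `< 0.5` mL/kg/h,
  stage 2 if the 12 h rate `< 0.5`, stage 3 if the 24 h rate `< 0.3` or the
  12 h rate is exactly 0 (anuria); thresholds are strict. If no weight has
  been charted, UO staging is missing. A rate is also treated as not
  computable until a full lookback window fits inside the stay (`t ≥ W`):
  without this rule, partially observed windows just after admission stage
  nearly every stay, and the prevalent-AKI exclusion would annihilate the
  cohort.
* **RRT.** Any started episode forces stage 3 from its start time.

The overall stage is the maximum over computable components (not-computable
counts as 0), and the **onset** is the earliest assessment time with stage
≥ 1. The deliberately excluded KDIGO rule is the absolute SCr ≥ 4.0 mg/dL
stage-3 criterion: staging here is built from the rise/ratio/RRT criteria
only, so a chronically elevated but stable creatinine is not labelled as
incident AKI.

Causality is a package invariant, not an aspiration: `assess_kdigo(stay, t)`
uses measurements at or before `t` for current values and strictly before
`t` for baselines, and the test suite perturbs future data and asserts that
past stages never move. The vectorized labeler (`assess_cohort()`) is
checked for exact equality against the scalar per-timestamp evaluation on a
50-stay cohort.

## 2. Rolling windows and leakage control

Each eligible stay is expanded into windows with a 12 h feature window, a
2 h gap, a 24 h outcome horizon, and a 6 h stride. Cutoffs start at 12 h
(one full feature window after admission — the first cutoff time was an open
choice) and continue while `cutoff + gap ≤ min(onset, discharge)`, which
censors each stay at its first incident AKI. The label is 1 iff the onset
falls in `[cutoff + 2, cutoff + 26)`; an onset exactly at the gap end is
kept and positive (half-open intervals everywhere, hours from admission,
`t = 0` at admission). Windows whose horizon extends past discharge are kept
and labelled from observed data — dropping them would bias against short
stays.

Exclusions mirror standard cohort assembly: age outside 18–88 or masked,
RRT active at ICU entry, onset before the first cutoff-plus-gap (prevalent
AKI), missing ESKD/baseline status, stay shorter than one feature window
plus gap. Each stay is logged once with the first triggered reason, in that
priority order (the order itself was unstated; the enum order was adopted).

Cross-validation folds partition *patients*, not windows: every window of a
patient, across stays, shares one fold. Fold assignment shuffles patients
under a seed and deals round-robin, so fold sizes differ by at most one
patient.

## 3. Features

Features summarize only data strictly before the cutoff. Three families:

* 12 h window summaries (mean/sd/min/max/last) of vitals and labs;
* long-lookback trends: 48 h (vitals) and 72 h (labs) OLS slopes, and the
  **piecewise slope change** (PSC): fit a continuous two-segment linear
  model with a single breakpoint chosen by least squares over interior
  observed timestamps (≥ 2 points strictly on each side) and report
  `slope₂ − slope₁`. PSC is missing below 4 points; the breakpoint search is
  exhaustive (series are short) rather than information-criterion based.
  Trend lookbacks reach beyond the 12 h feature window but never beyond the
  cutoff, preserving the leakage contract;
* urine-output totals and weight-normalized rates, vasopressor exposure
  (active flag and maximum infusion dose in-window), and statics (age,
  weight, sex, race, unit type, comorbidity flags).

Missing values are never imputed — the boosted trees route them natively,
and the sparsity pattern itself (labs ordered when concern is high) carries
signal. Screening, performed on training rows only, drops features with
more than 50% missingness or near-zero variance (dominant value share
> 99%, an operationalization chosen here), and *reports* collinear pairs
(|Pearson| or |Spearman| > 0.95) without dropping them — collinearity is
assessed, not pruned. Categorical vocabularies are learned on training rows;
unseen validation levels encode as all-zero indicators.

## 4. Model

The learner is XGBoost (`binary:logistic`) with per-feature monotone
constraints encoding physiology: creatinine, BUN and vasopressor-dose
features may only increase predicted risk (+1), urine-output features may
only decrease it (−1), everything else is unconstrained. `enforce_monotone()`
verifies the constraints post hoc by sweeping each constrained feature
across its observed range on sampled rows.

Hyperparameters are chosen by grid search maximizing mean out-of-fold AUC
under the patient-grouped folds. The shipped default grid is small (depth
4/6, learning rate 0.1, subsampling 0.8, minimum child weight 5) because the
original grid is unreported; it is configuration, not substance. Tree count
is fixed (200) rather than early-stopped: stopping on the held-out fold's
loss would let that fold's labels influence its own out-of-fold predictions,
and the package treats "permuting a validation fold's labels does not change
its predictions" as a hard invariant (tested). Early stopping remains
available as an option.

Feature selection ranks features by mean |SHAP| over out-of-fold rows (each
fold's model explains its own held-out rows; fold means pooled by simple
average — the pooling rule was unstated), keeps the top *k* (default 61) and
refits, reporting the out-of-fold AUC delta. Platt recalibration fits
`label ~ qlogis(raw)` on out-of-fold predictions; operating on the logit of
the probability (not the margin) makes the map idempotent, and a ridge
Newton fallback handles separable sets. A constant input degenerates to an
intercept-only fit mapping to the observed prevalence. The operating
threshold maximizes F2 over observed out-of-fold risks, ties broken toward
the smaller threshold (higher sensitivity).

## 5. Evaluation

Discrimination (tie-corrected Mann–Whitney AUC, step-interpolated AUPRC),
threshold metrics (alert iff `risk ≥ pt`, closed on the left; undefined
metrics are flagged `NA`, never silently zero), calibration (logistic slope
and intercept, CITL from the offset model with slope fixed at 1, ECE over 10
equal-width bins — the binning rule was unstated), and decision curves:

```
NB(model)     = TP/N − (FP/N) · pt/(1 − pt)
NB(treat-all) = π − (1 − π) · pt/(1 − pt)
```

At `pt = 0.125` the false-positive weight is `0.125/0.875 = 0.143`; with
window prevalences 0.171 and 0.142 the treat-all net benefit is 0.053 and
0.019 — the package's acceptance script recomputes exactly these. Confidence
intervals come from a percentile bootstrap resampling patients (clusters)
with replacement, 2000 replicates by default; BCa was deliberately not
implemented. Subgroup AUCs are compared with an unpaired DeLong test
(placement-value variances, two-sided normal reference, Bonferroni across
the comparison family), treating subgroup and complement as independent
samples. Covariate balance uses ASMD with the pooled-variance denominator.

Event-level alert analytics: an alert is any window whose recalibrated risk
crosses the threshold; it is a true positive when its stay's onset lies
within the alert's own label interval, and otherwise categorized by time
from cutoff to onset (≤ 48 h, ≤ 72 h, > 72 h, or no AKI; the first bin's
lower edge is the 26 h horizon end, not 24 h, because closer onsets are true
positives by construction). Lead time runs from the prediction cutoff — the
moment the prediction is issued — to onset (anchoring at the gap end was the
alternative), with strict `>` bins at 6/12/18/24 h evaluated on each event's
*first* true-positive alert. Burden metrics count alerts per patient-day and
per 12 h shift (= half the per-day rate), time under alert as the union of
per-alert coverage intervals `[cutoff, cutoff + 26)` (raw, discharge-capped,
and gap-excluded variants, since whether the gap counts is ambiguous),
repeat alerts (issued while a previous alert's coverage is active), and the
fractions of stays with ≥ 1 and ≥ 2 alerts.

## 6. The synthetic cohort generator

The generator emulates the *structure* of credentialed ICU databases without
reproducing any real data: stays/demographics, comorbidity flags, seven
vital streams, eleven lab streams, urine-output events, weight records,
treatment exposures and RRT episodes, as delimited tables with hours from
admission.

**Mechanics.** Each stay draws dense hourly latent trajectories
(piecewise-linear plus Gaussian noise — simplicity over realism; enough to
exercise slope and PSC features). A latent renal *insult* time is drawn from
a per-stay constant hazard whose log is a baseline plus
`Σ effect × driver` over five drivers: a hypotension-prone phenotype
(`map_downtrend`), an oliguria-prone phenotype (`low_uo`), sepsis, CKD, and
age (per decade above 65). After the insult, creatinine rises fast enough to
cross the 0.3 mg/dL criterion within ~1–2 h of the rise onset and then
climbs to a plateau multiplier drawn from a configurable stage mix
(1.5–1.9× / 2.0–2.9× / ≥ 3×), BUN follows, and a configurable fraction of
insult stays become oliguric — so at least one KDIGO criterion becomes
satisfiable unless discharge intervenes. Urine output is generated as a
latent rate in mL/kg/h realized as charted events whose volume accumulates
since the previous charted event (conserving volume; plain thinning would
bias rolling rates low), and weight is drawn at admission with an optional
mid-stay remeasurement, exercising the weight-lookup rule.

**Effect sizes govern both hazard and expression.** This is the central
design decision. An effect size scales the driver's log-hazard contribution
*and* the amplitude of its observable precursor: the falling mean arterial
pressure (and sympathetic heart-rate rise) over the ~18 h before the insult,
the pre-insult urine-output decline, the chronic phenotype correlates
(lower baseline MAP, lower baseline urine rate), and the probability of
prodrome-accompanying vasopressor support. Consequently a configuration with
all effects zero plants *no* predictive signal beyond the short sub-threshold
phases of the onset dynamics themselves, and the full pipeline's held-out
AUC on such a null cohort sits near 0.5 (tested at three seeds). With the
strong-effect configuration (2.5/2.5/2.0/2.0/0.8, baseline hazard 5 × 10⁻⁴)
the planted signal is recoverable: grouped-CV out-of-fold AUC above 0.80 at
2000 stays, with SHAP selection retaining every planted driver family.

**Missingness is informative by construction.** Vitals and labs are
Bernoulli-sampled from the hourly latent grid at per-stream base rates
(defaults: vitals 0.8/h, labs 0.14/h, urine charting 0.95/h), and after the
insult the sampling rate is multiplied by a severity multiplier (default 2) —
sicker patients are measured more often, the classic MNAR ordering pattern.
RRT episodes, weights and static fields are never thinned.

**Calibration.** `calibrate_prevalence()` bisects the baseline hazard (on
the log scale, under common random numbers) until the realized window-level
label prevalence after the full labelling/exclusion/windowing pipeline is
within ±2 percentage points of a target, evaluated on ≥ 500 stays. The
default baseline hazard (3.6 × 10⁻³/h with moderate default effects) was set
once this way to land the default cohort near the ~12% development-regime
window prevalence; the strong- and null-effect study configurations are
fixed conditions, not dials.

**What passing tests establish — and what they do not.** The synthetic
cohorts share the real databases' *structure* (irregular sampling, MNAR
ordering, censoring, prevalence regime, physiologic precursors) but not
their generating physiology: trajectories are piecewise-linear, the hazard
is constant within stay, drivers are independent, and within-stay sampling
frequencies are plausible guesses rather than measurements (the source
cohorts are characterized by missingness percentages, not sampling rates).
Green tests therefore establish that the pipeline is *correct* (labels are
causal and leak-free, metrics match brute-force oracles, constraints hold,
recoverable signal is recovered, null signal is not invented) — they do not
establish clinical performance on real ICU data, and no number produced on
synthetic cohorts should be quoted as such.

## 7. Numerical choices and degenerate inputs

* All intervals are half-open `[start, end)`; the time axis is continuous
  hours from ICU admission.
* OLS slopes need ≥ 2 points with distinct times; PSC needs ≥ 4 points and
  solves each candidate breakpoint's 3 × 3 normal equations in closed form
  (Cramer's rule over suffix sums), taking the minimum-RSS candidate.
* Risks of exactly 0/1 are clipped to `[10⁻⁶, 1 − 10⁻⁶]` (with a warning)
  before logit transforms.
* Threshold ties break toward the smaller threshold; grid-search ties toward
  the earlier grid point.
* Bootstrap replicates on which a statistic is undefined (e.g. a resample
  with one class) are dropped and counted, not zero-filled.
* One master seed drives fold assignment, booster seeding and the bootstrap;
  per-stay generator substreams are derived by counter-based splitting so a
  stay's data are invariant to cohort size.
* Problem sizes in the test suite (50-stay oracle cohorts, 2000-stay planted
  and 1200-stay null runs at three seeds each, 500-repetition coverage study
  at 200 bootstrap replicates) were chosen to make the stochastic checks
  stable at desk scale.

## 8. Known limitations

* The KDIGO SCr ≥ 4.0 mg/dL criterion is excluded (see §1); cohorts with
  frequent fulminant presentations would be staged later than a bedside
  nephrologist would stage them.
* Death before the horizon end is treated as an ordinary negative when no
  onset occurs — no competing-risk handling.
* Recurrent AKI is out of scope: stays are censored at first onset.
* Platt scaling is the only recalibration pathway; no centre-specific or
  hierarchical recalibration.
* The interface is the R API (`run_pipeline()`, `run_sensitivity_suite()`
  and the stage functions); there is no shell entry point.
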
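---
title: "Methods: from duty-cycled smartphone sensors to depression-severity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from duty-cycled smartphone sensors to depression-severity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`phenotrack` implements a complete digital-phenotyping analysis for
longitudinal depression studies: raw duty-cycled GPS and accelerometer
streams plus phone surveys go in; daily mobility/activity summaries, weekly
per-visit feature vectors, and leave-one-subject-out (LOSO) prediction of
clinician-rated MADRS scores come out. Because raw clinical sensor data of
this kind cannot be shared publicly, the package ships a synthetic-cohort
simulator with fully known generating parameters; every stage of the
pipeline is validated against that recoverable ground truth.

The pipeline stages are:

1. **Simulation** (`sim_config()`, `simulate_cohort()`): latent severity
   trajectories, clinical assessments, dense ground-truth movement and
   activity, and duty-cycled, gap-ridden sensor observations.
2. **Ingestion** (`read_gps()` and friends): delimited-text layouts with
   schema validation and malformed-row accounting.
3. **GPS mobility** (`mobility_daily()`): planar projection, flight/pause
   segmentation, trajectory imputation, home and significant-location
   detection, 14 daily mobility statistics.
4. **Accelerometer activity** (`minute_activity()`, `daily_activity()`,
   `hourly_activity_curve()`): per-minute activity scoring and hourly
   weekday/weekend curves.
5. **Aggregation** (`weekly_feature_vector()`, `analysis_table()`): 32
   weekly passive statistics per visit, PHQ-8 attachment, completeness and
   communication-log accounting.
6. **Modelling** (`fit_madrs()`, `loso_cv()`, `run_model_zoo()`): PCA
   reduction, random-intercept linear mixed models, LOSO cross-validated
   RMSE, and the A-F model zoo across covariate tiers.

# The cohort model

## Study design

The default `sim_config()` emulates an 8-week transdiagnostic outpatient
study: four diagnostic groups — healthy controls (HC, n = 11), major
depressive disorder (MDD, n = 10), bipolar disorder (BP, n = 10), and
schizophrenia/schizoaffective disorder (SCZ, n = 10) — with a baseline
visit and four biweekly follow-ups (five clinic MADRS ratings), weekly
in-app PHQ-8 surveys delivered on Saturdays, GPS cycled 2 min on / 10 min
off, and the accelerometer cycled 10 s on / 10 s off. A configurable
fraction of subjects (3/41 by default) drops out after the first follow-up.

## Latent severity

Each subject carries a latent depression severity on the MADRS scale
(0-60), evolving as a daily AR(1) process that mean-reverts to a
subject-level anchor:

$$x_{i,t} = m_i + \phi\,(x_{i,t-1} - m_i) + \varepsilon_{i,t},\qquad
  m_i \sim N(\mu_g, \sigma_{b,g}^2),\quad
  \varepsilon \sim N\!\big(0, \sigma_{w,g}^2 (1-\phi^2)\big),$$

with $\phi = 0.95$ per day. We anchor at the *subject* level rather than
letting every subject revert to the group mean: group-level reversion would
force the within-subject variance to equal the full between-subject spread
(about 13 MADRS points for the MDD group), i.e. implausibly wild biweekly
swings. The within-subject stationary SD is capped at 2 points by default
(`sigma_within_max`), matching the modest visit-to-visit change a clinical
cohort shows over 8 weeks; the between-subject SD absorbs the remainder.

Group anchors are calibrated on the *observed* scale. MADRS is
floor-censored at 0, and the healthy-control distribution sits on that
floor (target mean 0.7, SD 1.2). `censored_normal_params()` solves for
latent normal parameters whose censored moments $E[\max(X,0)]$,
$SD[\max(X,0)]$ match the target, so simulated group means reproduce the
anchors at any group size. A plain normal with the printed moments plus
clipping would bias the HC mean upward by several tenths of a point. A
small residual bias (≈ +0.3 for HC) remains because rater noise is added
*after* the severity floor; it is well inside the Monte-Carlo error at the
cohort's group sizes.

Observed scores are `MADRS = clip(round(x + rater noise), 0, 60)` with
rater SD 1, and `PHQ-8 = clip(round(0.4 x + noise), 0, 24)` with noise SD 2
(≈ the PHQ-8's standard error of measurement), allocated to 8 items in
[0, 3] by largest remainder — only totals are analyzed downstream, so the
item split need only satisfy its range invariants.

## Movement and activity

A day's ground-truth path alternates pauses and straight-line flights
between home and 2-4 subject-specific away anchors (0.5-5 km from home).
Excursion counts are Poisson with rate
$\lambda = \lambda_0 e^{\beta_{trips}\, x}$, and away-pause durations are
log-normal scaled by $e^{\beta_{away}\, x}$; with the default negative
couplings, expected distance traveled decreases and home time increases
monotonically in severity, emulating the spatial-isolation signature of
depression. With couplings set to zero the path is independent of severity
under the same random substream.

Accelerometer activity follows a 24-hour profile (near zero overnight,
rising from 7 a.m., peaking 9 a.m.-1 p.m.) scaled by
$e^{\beta_{act}\, x}$; active minutes add high-variance oscillation to the
1 g gravity signal.

Ground-truth daily metrics (distance, home time, radius of gyration,
diameter, pause fraction, active fraction) are computed *analytically* from
the continuous segment representation — closed-form time integrals, no
sampling — and stored with the cohort, so the observation-based feature
extractor can be checked against them exactly. The package asserts
agreement within 1% when the extractor runs on the dense noise-free 1 Hz
path.

All randomness flows from one root seed through named substreams
(`derive_seed(seed, subject, component, day)`), so identical configurations
give byte-identical cohorts and any component can be regenerated in
isolation.

## What the simulator does and does not emulate

It emulates: duty cycling anchored at local midnight, shared phone-outage
gaps (daily probability 0.15, mean 6 h — chosen so per-subject completeness
is variable but mostly above 0.5, as in real deployments), GPS position
noise (3 m SD, coherent with the 10 m pause radius after accuracy
filtering), survey non-completion (0.95 declining to 0.80) and lateness,
early dropout, and Android-only call logs with heavier calling in the
clinical groups. It does not emulate: iOS/Android sampling-fidelity
differences, battery dynamics, urban map structure (movement is
straight-line), phone-not-carried gaps distinct from outages, or the daily
4-item mood survey. Passing tests therefore demonstrate correctness of the
pipeline's accounting and estimators under a *plausible* behavioural model,
not performance on real traces.

# GPS processing

## Projection

Fixes with reported accuracy worse than 250 m are discarded, then
coordinates are projected to a local plane by an equirectangular projection
about the subject's median latitude/longitude (exact inverse available).
At daily-mobility scale (< 50 km) the projection error is negligible
relative to GPS noise.

## Flights, pauses, gaps

Within observed stretches, runs of consecutive points that stay within
`pause_radius_m` (10 m) of their running centroid for at least
`min_pause_s` (30 s) collapse to a pause at the centroid; remaining motion
becomes straight-line flights between retained points. Point spacings
larger than one full duty cycle (720 s) — a missed on-cycle or an outage —
open an unobserved *gap* carrying its known endpoint positions; the regular
600 s off-cycle spacing is deliberately below the threshold and is bridged
as normal motion, which is what makes duty-cycled traces segmentable at
all.

## Imputation

Gaps are filled by one of two methods. *Linear* draws a single
straight-line flight across the gap. *Resampling* (the default) draws the
subject's own observed flights and pauses as donors — weighted by
exponential decay in circular time-of-day distance (scale 3 h) with a 2x
bonus for same day-type donors — orients drawn flights toward the gap's
known endpoint with angular noise (never overshooting), and forces the
final segment to land exactly on the endpoint. We read the donor-weight
"temporal nearness" as time-of-day distance rather than absolute time:
with a 3 h decay on absolute time, donors from other days would carry
weight $e^{-8}$ and the pool would collapse to the same day; time-of-day
matching keeps the diurnal structure of behaviour while using the whole
trace. Every imputed subsequence begins and ends exactly at the observed
gap endpoints.

The package's imputation benchmark (`imputation_benchmark()`) simulates
days, removes an additional contiguous 30-70% block of each day, and
compares feature errors: resampling beats linear interpolation by roughly
an order of magnitude in mean normalized feature error at these settings,
driven by flight-duration and pause-probability statistics (a linear fill
is one implausible hours-long flight), with consistent but smaller gains on
distance-type features.

## Home, significant locations, daily features

Home is the centroid of the pause cluster carrying the most nighttime
(21:00-06:00) pause time. Significant locations are found by time-weighted
k-means (Lloyd's algorithm with deterministic farthest-point
initialization), growing k from 1 until every pause lies within 200 m of
its centroid or k reaches 10. `stats::kmeans` is not used because it
cannot weight points; pause *time*, not pause *count*, is what makes a
place significant.

The 14 daily features use the imputed (complete) trajectory — except
missing minutes, which count raw observation against the duty-cycle
schedule (240 observable GPS minutes/day under 2/10). Radius of gyration
and home time are computed by exact line integrals over segments rather
than by discretizing positions. Flight-moment SDs use the population
convention so a single-flight day has SD 0 rather than NA. Days with zero
observed minutes yield all-missing features (never imputed-through): the
weekly aggregation then sees no value, mirroring the principle that
absence is encoded by the missing-minute features, not by fabricated
zeros.

The two routine features compare days with each other: each day is reduced
to 48 half-hour representative positions; similarity of two days is the
fraction of co-observed bins within 500 m; circadian routine is a day's
mean similarity to the subject's other days, weekend-weekday routine its
mean similarity to days of the opposite type. These definitions are a
documented stand-in for supplement-deferred formulas in the source
literature; they are config-exposed (`routine_threshold_m`,
`routine_bin_min`) and validated by construction-based tests.

# Accelerometer processing

A minute is *observed* if at least 5 samples fall in it (the 10 s on /
10 s off cycle guarantees every minute is observable) and *active* if the
SD of the acceleration magnitude over its samples exceeds 0.1 g.
Magnitude-SD scoring is orientation-invariant and platform-neutral; the
threshold and minimum sample count are declared stand-ins for
supplement-deferred constants and are config-exposed. Hourly curves are
ratio estimators — active observed minutes over observed minutes, pooled
across days — which keeps them invariant to duplicating whole days and
avoids overweighting hours in which data happened to be collected. Daily
activity level is active/observed minutes; missing minutes are
1440 − observed.

# Aggregation

For each follow-up visit, the 7 local days *strictly preceding* the visit
date (the visit day excluded — the window must be fully in the past at
assessment time) are aggregated into 32 statistics: a weekday mean and a
weekend mean for each of the 15 daily feature families (14 GPS + activity
level), plus GPS and accelerometer missing-minute totals over the window.
Missing days contribute nothing to means and their full expected minutes
to the totals. The PHQ-8 predictor is the completed survey with the latest
completion timestamp at or before the visit (completion, not delivery: the
score exists only once completed).

Completeness follows the expected-minute convention: accelerometer
observed minutes over all window minutes; GPS observed minutes over
window minutes times the duty-cycle on-fraction (1/6). Survey completion
applies the late-completion reassignment rule (a completion is credited to
the latest survey already delivered) and the weeks histogram counts at
most one completion per survey week.

# Modelling

The 32 weekly statistics are z-scored by training mean/SD and reduced by
PCA; constant features are dropped with a warning, and component signs are
anchored so the weekend distance-traveled loading is nonnegative. Models
A-F use as phone-based predictors: PHQ-8 (A), PC1 (B), both (C), none (D),
PC1+PC2 (E), and raw weekend distance traveled (F); each is crossed with
three covariate tiers (nothing; age + sex + diagnostic category with
healthy-control reference; those plus baseline MADRS).

Fitting is a random-intercept linear mixed model per subject, by maximum
likelihood rather than REML: predictions use the fixed effects only (an
unseen subject's random intercept is zero), and ML keeps likelihoods
comparable across folds with different fixed-effect sets. Rows missing any
predictor are excluded from fitting and from scoring, with counts
recorded.

LOSO-CV holds out each subject, refits everything — including the feature
standardizer and PCA loadings — inside the training fold, predicts the
held-out visits from fixed effects, and averages *per-subject* RMSEs (not
pooled). A `pca_global = TRUE` switch instead fits the PCA once on all
subjects, reproducing the descriptive convention in which the full-data
first component is examined; the honest per-fold refit is the default.
Whether to refit per fold is genuinely ambiguous in the source literature,
which is why both are provided.

Parameter-recovery calibration: with data generated from the model itself
(40 subjects × 4 visits, σ_b = 3, σ_e = 4), fixed-effect estimates cover
the truth within 3 SEs in ≥ 95% of replicates, and the LOSO average RMSE
sits within 15% of $\sqrt{\sigma_b^2 + \sigma_e^2}$ — slightly below it on
average, because per-subject RMSEs are concave-averaged (Jensen) and
n = 40 estimation error is second-order.

No statistical model comparisons are reported — the package reports model
fit (RMSE grids), matching the design philosophy of presenting fit rather
than tests in exploratory digital-phenotyping work.

# Numerical and design choices

- **Timestamps** are UTC epoch milliseconds; a per-subject IANA timezone
  governs all day/hour binning. Day = [00:00, 24:00) local; weekend =
  Saturday + Sunday. Duty-cycle phase anchors at local midnight (the
  convention is unstated in the source literature; midnight anchoring makes
  runs reproducible).
- **Degenerate inputs**: empty streams yield empty segmentations; a
  single-fix day becomes a zero-length pause; gaps with no donors fall
  back to linear imputation with a warning; subjects without nighttime
  pauses have undefined home and missing home-dependent features; fewer
  than 2 complete-case subjects is a fitting error.
- **Ties**: k-means assignment breaks ties by first index; farthest-point
  initialization breaks exact distance ties by seeded sampling.
- **Problem sizes**: the shipped validation experiments use a 4-group,
  41-subject, 8-week cohort for the end-to-end run; 100 simulated days for
  the imputation benchmark; 200 replicates at 40 × 4 for coefficient
  coverage. These match the emulated study's scale while keeping a full
  validation run in the minutes range on a single core.

# Known limitations

- Movement is straight-line between anchors; no road networks, transit, or
  points of interest, so absolute feature values (e.g. daily distance) are
  stylized even though their severity couplings are realistic.
- The activity classifier is a magnitude-SD threshold, not a validated
  human-activity-recognition model; it separates the simulator's rest and
  active regimes essentially perfectly, which real accelerometry would
  not.
- Routine-feature definitions are package conventions (documented above),
  not reproductions of unpublished supplementary formulas.
- With very sparse observation (< ~10% of a day) the imputed trajectory
  degrades toward the donor pool's average behaviour; predictors derived
  from such days are accordingly unreliable, which is why missing-minute
  totals are carried as first-class features.
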
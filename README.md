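# phenotrack

Digital phenotyping of depressive symptoms from smartphone sensor data.

`phenotrack` is an R package for researchers running longitudinal mental
health studies in which participants carry a study app that samples GPS and
accelerometer data on a duty cycle (2 min on / 10 min off for GPS, 10 s on /
10 s off for the accelerometer), answers weekly in-app PHQ-8 surveys, and is
rated in clinic on the Montgomery–Åsberg Depression Rating Scale (MADRS,
0–60) at biweekly visits. The package turns those raw, gap-ridden streams
into interpretable behavioural summaries and asks the study's central
question: how well do passive measures predict clinician-rated depression
severity, compared with phone self-report?

Because raw clinical sensor data of this kind cannot be released, the
package also ships a synthetic-cohort simulator with fully known generating
parameters (latent severity trajectories coupled to movement and activity),
so that every stage of the pipeline is validated against recoverable ground
truth.

## What it computes

**Daily mobility statistics** from duty-cycled GPS, after decomposing each
trace into *flights* (approximately linear moves) and *pauses* (dwells
within a 10 m radius) and imputing unobserved intervals by resampling the
subject's own observed flights and pauses (straight-line interpolation is
provided as the comparison baseline — the benchmark shows roughly an
order-of-magnitude larger feature error): number of significant locations
(time-weighted k-means over pauses), time at home, distance traveled,
maximum diameter, maximum home distance, radius of gyration

&nbsp;&nbsp;&nbsp;&nbsp;$r_g = \sqrt{\tfrac{1}{T}\int_0^T \lVert p(t) - \bar p \rVert^2\,dt},$

flight length/duration moments, probability of pause, significant-location
entropy $-\sum_i p_i \ln p_i$ over pause-time shares, and circadian /
weekend–weekday routine similarities.

**Daily activity** from the accelerometer: a minute is active if the SD of
the acceleration magnitude over its samples exceeds 0.1 g; daily activity
level and hourly weekday/weekend curves are observation-weighted ratios.

**Weekly feature vectors**: for each follow-up visit, the 7 preceding days
are reduced to 32 statistics (weekday and weekend means of 15 daily feature
families, plus GPS and accelerometer missing-minute totals).

**Prediction**: random-intercept linear mixed models

&nbsp;&nbsp;&nbsp;&nbsp;$\mathrm{MADRS}_{ij} = x_{ij}^\top\beta + b_i + \varepsilon_{ij},
\qquad b_i \sim N(0,\sigma_b^2),$

fitted by maximum likelihood, evaluated by leave-one-subject-out
cross-validation with fixed-effects-only prediction, and reported as the
average of per-subject RMSEs. Models A–F (PHQ-8 / first passive principal
component / both / neither / PC1+PC2 / weekend distance) are crossed with
three covariate tiers (none; demographics; demographics + baseline MADRS)
to form an RMSE grid.

## Worked example

```r
library(phenotrack)

cfg <- sim_config(n_per_group = c(HC = 3, MDD = 3, BP = 3, SCZ = 3),
                  baseline_means = c(HC = 0.7, MDD = 20, BP = 9.7, SCZ = 6.2),
                  baseline_sds  = c(HC = 1.2, MDD = 12.7, BP = 10.6, SCZ = 5.4),
                  seed = 8)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic cohort: 12 subjects (BP=3, HC=3, MDD=3, SCZ=3), 57 visits, 90 survey rows
#>   GPS rows: 890,471; accel rows: 5,343,028; truth days: 642

mcfg  <- mobility_config(seed = 8)
feats <- extract_features(cohort, mcfg)   # daily mobility + activity tables
tab   <- analysis_table(cohort, feats, mcfg)  # one row per follow-up visit

fit <- fit_madrs(tab, model = "A", tier = "full")
fit
#> Model A (+full covariates): linear mixed model, ML
#>   45 visits, 12 subjects (0 rows excluded for missing predictors)
#>   random-intercept SD 1.28, residual SD 1.51
#>    (Intercept)           phq8 baseline_madrs            age           sexM
#>          2.867          0.231          0.916         -0.048         -1.593
#>    diagnosisBP   diagnosisMDD   diagnosisSCZ
#>          1.155          1.909         -0.464

loso_cv(tab, model = "B", tier = "full")
#> Model B (+full): LOSO-CV average RMSE 3.29 over 12 subjects
```

The fitted coefficients behave as the generating model dictates: baseline
MADRS carries most of the between-subject signal (0.92 per point), PHQ-8
adds within-subject tracking (0.23 per point on the 0–24 scale), and the
residual SD is small because within-subject severity drifts slowly. The
LOSO RMSE is on the MADRS 0–60 scale: predictions for an entirely unseen
subject are off by about 3 points on average in this small example.

`run_model_zoo(tab)` produces the full 6-model × 3-tier RMSE grid, and
`completeness_report(cohort)`, `hourly_activity_curve()`, and
`comm_log_stats()` reproduce the study's data-completeness accounting,
hourly activity curves, and Android call-log summaries.

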
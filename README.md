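# drumkin

Arm kinematics and permutation inference for wrist-worn drumming sensors.

## What problem this solves

Motor function declines alongside — and often years before — cognitive
function, but people with moderate-to-severe dementia frequently cannot
complete standard motor assessments (maximal handgrip, range-of-motion
protocols) because of cognitive decline and apraxia.  Group drumming is
a motor task this population *can* sustain: the mallet rebounds off the
drum head and the rhythm entrains the movement.  A wrist-worn inertial
sensor (3-axis accelerometer + gyroscope at 20 Hz, worn like a
wristwatch on the dominant arm) turns each session into a quantitative
upper-limb assessment.

`drumkin` is for researchers and rehabilitation engineers who want to
compute and validate the two biomarkers of that assessment and relate
them to cognition in small cohorts:

* **Average arm velocity** —
  `mean[acos(V_t · V_{t−Δt}) / Δt] × r`, the mean angular speed of the
  wrist scaled by the forearm radius of gyration r = 0.223 m, with
  samples at or below a 0.1 m/s² linear-acceleration rest threshold
  excluded.
* **Average arm elevation angle** — θ_z = asin(V_t^(z)), the angle of
  the forearm-longitudinal axis above horizontal, summarized as the mean
  of per-second window maxima.

V_t is the gravity-referenced orientation unit vector, estimated by a
gyro-aided complementary filter with lever-arm compensation (see the
methods vignette for why accelerometer-only tilt sensing cannot track a
1.5 Hz swing).  On top of the biomarkers sits a permutation inference
layer built for n ≈ 16: Spearman correlations with exact
(exhaustively enumerated) permutation p-values for n ≤ 7 and seeded
fixed-count sampling otherwise, permutation multiple regression with
standardized β, VIF diagnostics, and an AIC model ladder for predicting
MMSE.  Because no raw cohort data are public, the package also ships a
synthetic-data module: a forearm-swing IMU simulator with analytic
ground truth and a Gaussian-copula cohort generator targeting the
published rank-correlation structure.

## Worked example

```r
library(drumkin)

# one subject's 60 s session, simulated with analytic ground truth
sim <- simulate_drumming_motion(motion_params(seed = 2))
summarize_kinematics(sim$stream)
#>   subject_id avg_velocity_ms avg_elevation_deg n_samples_total
#> 1  sim-seed2       0.2312483          24.89529            1201
#>   n_samples_rest_removed n_windows
#> 1                      0        60
```

The simulated swing (15° ± 10° at 1.5 Hz) has a definitional average
elevation of exactly 25° and an analytic average velocity of 0.2335 m/s;
the pipeline recovers 24.90° and 0.2312 m/s from the 20 Hz sensor
stream alone.

```r
# a pilot-style cohort (n = 16, 12 women, one missing handgrip value)
cohort <- simulate_cohort(cohort_params(seed = 5))
perm_spearman(cohort$avg_elevation_deg, cohort$mmse, n_perm = 9999, seed = 1)
#> Spearman rho = 0.7080 (n = 16), p = 0.0011, permutation p' = 0.0013 [9999 permutations]

# the full pipeline: cohort -> per-subject streams -> biomarkers ->
# descriptive report, correlation table, regression, AIC ladder
res <- run_pipeline(run_config(tempfile(), n_perm = 9999, seed = 20230525))
res$ladder
#>                                                       model k  n      rss      aic  best
#> 1                               grip_kg + avg_elevation_deg 2 15 134.5931 83.48125  TRUE
#> 2                         age + grip_kg + avg_elevation_deg 3 15 130.8984 85.06372 FALSE
#> 3                   age + sex + grip_kg + avg_elevation_deg 4 15 130.5697 87.02601 FALSE
#> 4 age + sex + grip_kg + avg_velocity_ms + avg_elevation_deg 5 15 123.4863 88.18936 FALSE
```

The ladder ranks candidate MMSE models by Gaussian-likelihood AIC
(lower is better); on this synthetic cohort the two-term handgrip +
elevation model wins, the same parsimonious structure the biomarker was
designed to expose.  `res$regression` holds the standardized β, t,
permutation p′ and VIF per term; `res$output_dir` contains the CSV
bundle plus a `manifest.json` that records every seed and parameter
needed to re-execute the run exactly.

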
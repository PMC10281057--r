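---
title: "Drumming kinematics as a digital biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drumming kinematics as a digital biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumkin)
```

## The problem

Standard motor assessments — maximal handgrip, range-of-motion tests —
require understanding and following instructions, which people with
moderate-to-severe dementia often cannot do because of cognitive decline
and apraxia.  Group drumming is different: the mallet rebounds off the
drum head, the rhythm entrains the movement, and residents who cannot
complete a grip test can still drum for a full session.  A wrist-worn
inertial sensor (3-axis accelerometer + 3-axis gyroscope, 20 Hz) worn
like a wristwatch on the dominant arm therefore offers an unobtrusive
window on upper-limb motor function, and — because motor decline tracks
and precedes cognitive decline — a candidate digital biomarker of
dementia severity.

This package implements the full chain: sensor CSV in, two kinematic
biomarkers out, and a permutation-based inference layer relating them to
cognitive (MMSE) and motor measures in small cohorts.

## The two biomarkers

**Average arm velocity (m/s).**  With $V_t$ a unit orientation vector per
sample and $\Delta t$ the sample period,

$$\bar v \;=\; \operatorname{mean}_t
  \left[\frac{\arccos\!\big(V_t \cdot V_{t-\Delta t}\big)}{\Delta t}\right]
  \times r ,$$

the mean angular speed of the wrist scaled by a radius of gyration
$r = 0.223$ m, the mean adult forearm length.  Samples whose linear
(gravity-removed) acceleration magnitude is at or below
0.1 m/s$^2$ are treated as non-exercise time and excluded, so pauses
between bouts do not dilute the average.

**Average arm elevation angle (degrees).**  With the device $z$-axis
along the forearm (wrist $\to$ elbow) and $\hat g_t$ the estimated "up"
direction in the device frame, the per-sample elevation is
$\theta_z = \arcsin \hat g_t^{(z)}$ — the angle of the forearm above
horizontal, negative when the hand hangs below the elbow.  The stream is
cut into consecutive non-overlapping 1 s windows anchored at the stream
start (the trailing partial window is discarded), and the biomarker is
the mean of the within-window maxima: how high the arm *reaches* each
second, not where it dwells.

## Estimating $V_t$: the design choice that matters

Only the sensors are specified, not the orientation algorithm, so the
package had to fix one.  The candidates:

1. **Low-passed accelerometer only** (exponential smoothing with time
   constant $\tau$, then normalization).  This is exact for static
   postures, but a first-order low-pass attenuates an oscillation of
   frequency $f$ by $1/\sqrt{1 + (2\pi f \tau)^2}$.  A drumming swing at
   1.5 Hz seen through $\tau = 1$ s keeps barely 10 % of its amplitude:
   the estimated orientation stops moving, the elevation maxima collapse
   toward the mean posture, and the velocity metric loses an order of
   magnitude.  No choice of $\tau$ rescues both metrics: small $\tau$
   admits the swing's own tangential/centripetal acceleration (up to
   $\sim$3.5 m/s$^2$, i.e. $\sim$19° of direction error) into the
   gravity estimate.
2. **Complementary (gyro-aided) filter**, the default: propagate
   $\hat g$ through the gyroscope rotation each sample period and apply
   the accelerometer as a slow correction with gain
   $\alpha = \Delta t / (\tau + \Delta t)$, $\tau = 1$ s.  The gyro
   carries the fast dynamics; the accelerometer only has to fix the slow
   drift, exactly the regime where its low-passed direction is
   trustworthy.

Two numerical refinements make the default meet its oracles at 20 Hz:

* **Angular increment quadrature.**  Integrating the gyro with the
  trapezoid rule attenuates each step angle by
  $(\omega h/2)\cot(\omega h/2)$ ($\approx -1.9$ % at 1.5 Hz, 20 Hz),
  which biases the velocity metric directly.  The filter instead uses a
  Simpson rule whose midpoint rate is cubic-interpolated from the
  neighboring gyro samples, reducing the step bias to below 0.1 %.
* **Lever-arm compensation.**  The biomarkers' own model is rotation
  about the elbow at radius $r$, so the rigid-rotation acceleration at
  the sensor, $\dot\omega \times p + \omega \times (\omega \times p)$
  with $p = (0, 0, -r)$, is predicted from the gyro (angular
  acceleration by central differences) and subtracted before the
  accelerometer is used as a gravity reference.  This removes the
  tangential/centripetal contamination at its source.  It anchors the
  estimator to the forearm-axis convention: metrics are then *not*
  invariant under an arbitrary relabeling of the device axes (the
  uncompensated estimator is, and `lever_arm_comp = FALSE` restores that
  property).

Accelerometer samples with magnitude below 0.5 m/s$^2$ (near free-fall)
carry no usable gravity reference and are flagged invalid.  Dot products
are clamped to $[-1, 1]$ before `acos`.  The rest threshold is applied to
$\lVert a - g \hat g_t \rVert$, never to the raw magnitude (which is
$\approx 9.8$ m/s$^2$ at rest).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `radius_m` | 0.223 | m | angular $\to$ linear velocity scale (mean forearm length) |
| `rest_threshold_ms2` | 0.1 | m/s$^2$ | non-exercise cutoff on linear acceleration |
| `window_s` | 1.0 | s | elevation window (mean of window maxima) |
| `gravity_ms2` | 9.80665 | m/s$^2$ | standard gravity |
| `gravity_tau_s` | 1.0 | s | accelerometer-correction time constant |
| `orientation_method` | complementary | — | gyro-aided vs accel-only $\hat g$ |
| `lever_arm_comp` | TRUE | — | subtract rigid-rotation acceleration at $p = (0,0,-r)$ |
| `min_accel_ms2` | 0.5 | m/s$^2$ | validity floor for the gravity reference |

The rest threshold is interpreted per sample (the alternative, per
window, is not implemented); the radius is fixed rather than
personalized.  On-disk gyro units are deg/s (the common wearable
convention); everything internal is SI (rad/s), and reported angles are
degrees.  Recording gaps longer than 5 nominal periods (250 ms at
20 Hz) are treated as breaks rather than Bluetooth jitter: the stream is
split there and the longest contiguous segment analyzed.

## Permutation inference

With $n = 16$ participants, parametric p-values lean hard on
distributional assumptions.  The package's inference layer is
permutation-based throughout:

* **Spearman correlations** (`perm_spearman`): mid-ranks everywhere; for
  $n \le 7$ all $n!$ permutations are enumerated and p$'$ is exact
  (perfect concordance at $n = 4$ gives exactly $1/24$); otherwise a
  fixed, seeded number of random permutations is drawn and the add-one
  rule $p' = (1 + k)/(n_{perm} + 1)$ keeps p$'$ off zero.  A fixed count
  (default 19 999) was chosen over sequential/adaptive stopping for
  bit-reproducibility.  The default alternative is one-sided (positive
  association), matching the directional hypothesis that better motor
  function accompanies better cognition; two-sided is a flag away.
* **Multiple regression** (`fit_perm_regression`): response and
  predictors are z-scored (binary sex is coded 0/1, then z-scored —
  coding first, scaling second), coefficients are standardized $\beta$,
  and per-term p$'$ compares $|t_j|$ under response permutation.  The
  Manly scheme (permute the raw response) is the default as the simplest
  scheme consistent with "permutation multiple regression";
  Freedman–Lane (permute reduced-model residuals per term) is available
  via `scheme =`.  Term p-values are two-sided, since standardized
  coefficients of a multi-predictor model carry no single pre-declared
  direction.
* **No multiplicity correction** is applied across the 55 pairwise
  correlations — the permutation test is used *instead of*
  Bonferroni/FDR-style control, which at this sample size trades type I
  for type II error; a Benjamini–Hochberg column is available as an
  optional post-hoc extra (`fdr = TRUE`).
* **Diagnostics**: $VIF_j = 1/(1 - R^2_j)$ from regressing predictor $j$
  on the rest (values $< 5$ read as no collinearity concern), and a
  model ladder ranked by Gaussian-likelihood AIC,
  $n\ln(RSS/n) + n\ln 2\pi + n + 2(k + 2)$.  The constant convention is
  fixed (and equals `stats::AIC`) so printed values are comparable
  run-to-run; only AIC *differences* are the contract.  Ladder
  candidates are fitted on rows complete across the union of terms so
  all candidates share one sample.

The pooled (Student) rather than Welch form is used for the
sex-difference column of the descriptive report because recomputing the
published pilot table from its printed summaries reproduces the printed
p-values only under the pooled form, and those comparisons are treated
as two-sided for the same reason, despite the one-sided convention of
the correlation analyses.  Recomputation from two-decimal printed
summaries carries an irreducible input-rounding error: all printed rows
reproduce to $\pm 0.002$ except the velocity row, whose female SD is
printed with a single decimal ("0.5"), which propagates to
$\approx \pm 0.005$ in p.

## The synthetic-data module

No raw per-participant data are public, so the package ships generators
with analytic ground truth; they are first-class, tested code.

**Motion** (`simulate_drumming_motion`): a single-axis swing about the
elbow, $\phi(t) = \phi_0 + A\sin(2\pi f t)$, with device-frame specific
force $(g\cos\phi - r\ddot\phi,\; 0,\; g\sin\phi + r\dot\phi^2)$ and
gyro $(0, \dot\phi, 0)$, plus Gaussian noise.  Defaults — $\phi_0 =
15°$, $A = 10°$, $f = 1.5$ Hz, 60 s at 20 Hz — describe a forearm held
above horizontal striking ~1.5 times per second; each 1 s window then
contains a full period, so the definitional average elevation is exactly
$\phi_0 + A = 25°$.  Noise defaults (0.01 m/s$^2$, 0.005 rad/s per
axis) are consumer-MEMS figures at a 10 Hz bandwidth; realistic device
noise must sit well below the 0.1 m/s$^2$ rest threshold for that
threshold to be meaningful, as it does on real hardware.  Rest segments
hold $\phi$ at $\phi_0$; entries and exits are smoothed by a 0.25 s
raised-cosine ramp because a physical forearm cannot change posture
discontinuously — without the ramp the simulated gyro would miss the
jump that the simulated orientation takes, an artifact of the generator
rather than a property of any device.  Ground truth evaluates the
*defining formulas* of both biomarkers on the analytic trajectory at
1 kHz; true rest labels are where the analytic motion acceleration
$r\sqrt{\smash[b]{\ddot\phi^2 + \dot\phi^4}}$ is at or below the
threshold.  The azimuthal component of real drumming is not modeled:
both biomarkers are functions of elevation and angular-step magnitude
only, so azimuth would add parameters without testable consequences.

**Cohort** (`simulate_cohort`): a Gaussian copula over the published
marginal means/SDs, targeting the published pairwise Spearman matrix via
$r = 2\sin(\pi\rho_s/6)$ with nearest-PSD repair, then Gaussian
marginals (rank correlations preserved).  MMSE is rounded and clipped to
$[0, 30]$, the daily-living ordinal to ranks 1–7, masses/days/angles to
their physical ranges; the 12:4 woman:man split is a seeded permutation
and one handgrip value is set missing, mirroring the participant who
could not perform the measurement (recorded as absent, not zero).  Sex
is generated independently of the other variables because no joint
tabulation with sex exists to target.

**What passing tests do and do not show.**  The generators reproduce the
*statistical* structure of the pilot study (marginals, rank
correlations, design) and the *mechanical* structure of a single-axis
swing.  Real drumming has variable tempo, multi-axis motion, soft-tissue
artifacts and device-specific noise spectra; recovery results on
synthetic data bound the method's behavior under the stated model, not
under every departure from it.

## Numerical choices and degenerate inputs

* Windows are anchored at the stream start; trailing partial windows are
  discarded; a window with no valid sample is dropped from the mean.
* An all-rest stream has no velocity (reported `NA`) but a valid
  elevation; the pipeline completes.
* Permutation p-values can never be 0; exhaustive enumeration includes
  the identity permutation.
* Perfect collinearity reports `Inf` VIF with a warning; rank-deficient
  design matrices name the dependent columns in the error.
* Tie handling is mid-ranks everywhere.
* All simulations are seeded; every pipeline stage derives a fixed
  sub-seed from the root seed, and reruns are byte-identical.

Test problem sizes were chosen to exercise each claim at pilot scale:
null calibration uses 1 000 replicate datasets at $n = 16$ with 999
permutations each; copula recovery uses $n = 10^4$ for the asymptotic
check and 1 000 pilot-sized replicates for the sampling distribution;
kinematic oracles use 60 s streams at 20 Hz against 1 kHz analytic
truth.

## Worked example

```{r example, eval = FALSE}
library(drumkin)

# one subject's session, simulated with ground truth
sim <- simulate_drumming_motion(motion_params(seed = 2))
summarize_kinematics(sim$stream)

# a pilot-style cohort and the elevation-MMSE association
cohort <- simulate_cohort(cohort_params(seed = 5))
perm_spearman(cohort$avg_elevation_deg, cohort$mmse,
              n_perm = 9999, seed = 1)

# the full pipeline
res <- run_pipeline(run_config(tempfile(), n_perm = 9999, seed = 20230525))
res$ladder
```

## Known limitations

* The orientation estimator assumes the rotation-about-the-elbow model
  whenever lever-arm compensation is on; shoulder-dominated movements
  violate $p = (0, 0, -r)$ and the compensation degrades toward the
  uncompensated filter.
* The published individual-level regression results (adjusted $R^2$,
  per-term $\beta$) cannot be verified without the raw cohort; they
  serve as schema and generator targets only.
* No drum-strike detection, stroke counting or rhythm analysis: tempo
  and rhythmic accuracy are explicitly unmeasured here.
* Axis conventions of specific commercial wearables differ; the CSV
  dialect fixes $z$ = forearm-longitudinal and users must map their
  device accordingly.
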
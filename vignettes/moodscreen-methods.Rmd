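---
title: "Screening for childhood internalizing disorders from waist-worn IMU data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for childhood internalizing disorders from waist-worn IMU data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodscreen)
```

## The problem

Internalizing disorders (anxiety, depression, trauma-related conditions) in
young children are easy to miss: symptoms face inward, so affected children
rarely produce the disruptive behavior that triggers a referral. A candidate
objective screen is a brief mood-induction task — the child walks with an
examiner toward a covered terrarium, anticipates an ambiguous threat, and is
startled when a (fake) snake is revealed — while a single inertial
measurement unit (IMU: 3-axis accelerometer + 3-axis gyroscope) worn at the
waist records their movement. Children with an internalizing diagnosis tend
to turn away from the threat during the anticipation period; the pipeline in
this package turns that behavioral signature into a classifier and evaluates
it the way a screening instrument should be evaluated.

`moodscreen` implements the complete chain: raw IMU signals to
world-referenced kinematics, phase segmentation, time-series features,
separability-based feature selection, leave-one-subject-out (LOSO)
cross-validated logistic classification, a permutation test against chance,
and a parent-questionnaire (CBCL) comparator — plus a synthetic cohort
simulator so every stage can be exercised and validated without access to
real child data.

## Signal processing

Raw recordings (nominally 300 Hz) are decimated to 100 Hz by integer-factor
sample picking and low-pass filtered with a 4th-order Butterworth IIR filter
at 20 Hz (`preprocess()`). Filtering is zero-phase (forward–backward) by
default: event-locked segmentation depends on the timing of the signal, and
zero-phase filtering is standard biomechanics practice; it squares the
magnitude response, so the effective stopband attenuation doubles. A causal
single-pass mode is available (`zero_phase = FALSE`). Because the filter is
a digital design (bilinear transform with cutoff pre-warping), its response
at frequency $f$ is

$$|H(f)|^2 = \left[1 + \left(\frac{\tan(\pi f/f_s)}{\tan(\pi f_c/f_s)}\right)^{2n}\right]^{-1},$$

not the analog $(1+(f/f_c)^{2n})^{-1}$; at 25 Hz the zero-phase gain is
0.072, and the test suite asserts the digital value.

Orientation is tracked by a complementary filter
(`estimate_orientation()`): per-sample strapdown integration of the
gyroscope, corrected each sample a fraction `accel_weight` of the way toward
the accelerometer-implied gravity direction. The correction axis is always
horizontal, so the accelerometer only ever adjusts tilt; heading (yaw) is
pure gyro integration. Without a magnetometer, yaw drifts — at typical
consumer-gyro bias this is a few degrees over the ≤ 90 s task, negligible
against the ~180° effect of interest, and accepting it avoids magnetometer
calibration problems indoors. Defaults: `accel_weight = 0.02` per sample at
100 Hz (≈ 0.5 s correction time constant — fast enough to follow postural
tilt, slow enough to reject motion acceleration), initialization from the
first 0.5 s mean accelerometer vector with yaw ≡ 0, and the correction is
skipped when the specific-force norm falls below 0.05 g (free fall). The
exact gains of the original instrument are not published, so they are
arguments, not constants.

`derive_channels()` resolves the signals in the world frame and emits the
six analysis channels: horizontal acceleration magnitude `ah` (m/s², ≥ 0),
gravity-removed vertical acceleration `av` (m/s²), horizontal
angular-velocity magnitude `omegah` (deg/s, ≥ 0), the signed vertical
angular-velocity component `omegav` (deg/s), tilt `alpha` (deg ∈ [0, 180])
and yaw `gamma` (deg). `gamma` is unwrapped (no ±180° jumps), referenced to
the first sample, and reported as absolute deviation from the initial
heading — the published trajectories are magnitudes on a 0–180° axis, and a
turn away from threat is equally meaningful in either direction. Internal
units are SI (1 g = 9.80665 m/s²) with angles in degrees.

## Phases and features

The task has three conceptual phases around the startle moment (time 0):
Potential Threat [−23, −3) s, Startle [−3, +3) s, Response Modulation
[+3, +23) s. Windows are half-open on the right so a boundary sample belongs
to the later phase; at 100 Hz the segments are exactly 2000 / 600 / 2000
samples. The startle moment is an annotation (event JSON), not detected from
the signal.

Each channel of each phase yields 29 features (`extract_channel_features()`),
174 per phase:

* 9 amplitude statistics — mean, RMS, skew, kurtosis, range, max, min, SD,
  peak-to-RMS (max |x| / RMS, 0 when RMS = 0);
* 7 spectral band powers — 0–0.5, 0.5–1.5, 1.5–5, 5–10, 10–15, 15–20 and
  > 20 Hz, computed on the one-sided periodogram of the mean-removed series
  (rectangular window, resolution 1/T = 0.05 Hz for a 20 s phase). Band
  edges are half-open `[lo, hi)` with the last band closed at Nyquist, so
  the seven powers partition total power exactly (a Parseval identity the
  tests assert);
* 12 spectral-peak values — locations and heights of the first 6 strict
  local maxima of the periodogram, ordered by ascending frequency. Ordering
  by frequency (rather than prominence) makes "the 6th peak" well defined;
  fewer than 6 peaks pad with (0, 0), and maxima below 10⁻¹² of the
  strongest bin are ignored as floating-point leakage;
* 1 autocorrelation value — the zero-lag height of the *biased, unnormalized*
  autocovariance, i.e. the mean squared deviation. A normalized
  autocorrelation is identically 1 at lag 0 and could never discriminate;
  the unnormalized estimator is a variance-type amplitude summary.

Kurtosis is the non-excess moment ratio (Gaussian → 3), matching the
convention of the numerical environment the original analysis used; skew and
kurtosis of a zero-variance series are defined as 0 so every feature is
finite on any input.

## Feature selection and classification

Features are ranked by a two-class Davies–Bouldin score
(`db_index()`): $(S_1 + S_2)/|c_1 - c_2|$ with class means $c_i$ and
mean-absolute-deviation scatters $S_i$ (the q = 1 form of the
Davies–Bouldin scatter; q = 2 is a config option). Lower is better;
coincident centroids score ∞, which also puts constant features last.
Scoring is univariate — each feature independently — with ties broken by
original column order so the ranking is reproducible. The 10 lowest-scoring
features enter an unregularized maximum-likelihood logistic regression.

Evaluation is leave-one-subject-out (`loso_evaluate()`): for each of the
n subjects, the remaining n − 1 form the training set; z-scoring parameters
(mean and sample SD, n − 1 divisor), the Davies–Bouldin ranking and the
logistic fit are all recomputed inside the fold, and the held-out subject is
transformed with training parameters only. A corruption test asserts the
no-leakage property directly. Implementation notes: fold means/SDs are
obtained by leave-one-out updates of the full-table column sums, and the
Davies–Bouldin ranking runs on the raw training columns — the score is
invariant under the per-feature affine map that z-scoring applies (also
asserted numerically) — so only the selected columns are standardized.
A fold whose training labels collapse to one class aborts with an explicit
error rather than silently predicting.

If the logistic MLE separates (fitted probabilities pinned at 0/1 or
non-convergence), the model is refit with a small ridge penalty
(λ = 10⁻⁴, intercept unpenalized) so coefficients stay finite; the result
carries a `separable` flag. With 10 standardized predictors and ~60
subjects, separation occurs regularly in permuted runs, so the fallback is a
load-bearing code path, not an ornament.

Hard predictions use score ≥ τ with τ = 0.5 by default; τ = 0.375 is the
screening-oriented secondary operating point (higher sensitivity at some
specificity cost) and is an argument throughout. The ROC is the empirical
curve over all distinct score thresholds; its trapezoidal area equals the
rank-sum (concordance) statistic with half-credit for ties, and the tests
check that identity against exhaustive pair counting and against an
independent ROC implementation.

## The chance test

The comparison against chance follows the published construction: the
observed error rate k/n is dressed with uncertainty by drawing m = 100
samples from Beta(k + 1, n − k + 1) — the Bayes–Laplace posterior, chosen
over Beta(k, n − k) because the latter is degenerate at k = 0; the shape is
an option. The null side re-runs the *entire* LOSO pipeline (selection and
standardization included) on m = 100 uniform label permutations. The two
samples are compared with a two-sided Wilcoxon signed-rank test on
index-paired differences (the published description names a "paired-sample
Mann–Whitney U-test", which is self-contradictory; the unpaired
Mann–Whitney variant is a flag).

A caveat that matters: this construction is anticonservative. All m
"observed" draws derive from a single realized error rate, so the rank test
treats one number's chance offset from the null median as m independent
confirmations, and on zero-effect data it rejects far more often than α.
The implementation is faithful to the construction — and the package also
reports `null_percentile`, the fraction of permutation errors at or below
the observed error, which is the classical (and calibrated) one-sided
permutation p-value. On null cohorts the percentile diagnostic rejects at
the nominal 5%; the distribution-comparison p-value does not, and the test
suite measures both behaviors rather than hiding the discrepancy.

## The questionnaire comparator

The Child Behavior Checklist (CBCL) yields normed T scores; screening
classifies a child positive when T ≥ 70 (manualized clinical cutoff) or
T ≥ 55 (conservative screening cutoff), inclusive at the boundary. Metrics
flow through the same confusion-matrix code as the sensor pipeline; the
continuous T score also gives a threshold-free AUC. Missing T scores are
excluded listwise per scale and the analyzed denominator is always reported
— published questionnaire tables are rarely consistent with the full sample
size, and a denominator printed next to every rate is the only honest way
to present such data.

## The synthetic cohort

`simulate_subject()` works inverse-first: a world-frame orientation
trajectory is prescribed, then differentiated into exact device-frame
gyroscope rates and used to resolve gravity into accelerometer readings —
so ground truth is known exactly and round-trip tests through the kinematics
module are meaningful to a couple of degrees.

Default study conditions (a `cohort_spec()`): 21 cases / 41 controls at
100 Hz, 52 s recordings with the startle at 28 s. Diagnosed children execute
a smooth logistic yaw turn beginning halfway through the Potential Threat
phase (~5 s duration), with final yaw ~N(160°, 30°) clamped to [90°, 180°];
controls wander with final yaw ~N(30°, 20°) clamped to [0°, 58°], below 60°
by construction. These centers mirror the published representative
trajectories (a case ending near 180°, a control below 60°). Both groups
receive an identical startle jolt — a 0.3 s, 11 Hz damped acceleration burst
— because the startle response itself was not discriminative. Ambient
realism comes from slow postural sway (2° tilt oscillation at 0.2–0.4 Hz
plus matching yaw wander), accelerometer noise (0.02 g SD) and gyroscope
noise (1 deg/s SD) — magnitudes typical of consumer MEMS sensors and a
standing child. Every subject draws from a deterministic substream of the
master seed, so cohorts are bitwise reproducible.

What the simulator does *not* emulate: gait and step impacts, fidgeting,
sensor bias/scale errors, magnetic disturbance, or any correlation structure
among the 174 features beyond what the shared kinematics induces. Passing
synthetic-recovery tests therefore shows the pipeline recovers a planted
yaw effect through the full signal chain at realistic noise levels — it does
not certify performance on real children, where effect sizes and artifact
structure are unknown. `simulate_feature_table()` additionally provides a
feature-level shortcut (i.i.d. noise with planted group gaps) used where
only the statistical stages are under test.

## Problem sizes in the test suite

The stochastic surfaces are sized to keep the full suite comfortably
rerunnable while leaving the statistical assertions meaningful: effect
recovery and zero-effect bands use 20 full-pipeline cohorts of 62 subjects
each; the planted-signal surface uses 100 replicates at the study's group
sizes (21/41) with one 3-SD feature among 40, and the type-I surface 100
replicates of 16-subject, 20-feature null cohorts — each replicate costs
101 complete LOSO runs (m = 100 permutations). Brute-force equivalences
(Davies–Bouldin, AUC pair-counting) run hundreds of randomized instances at
n ≤ 30, where the oracles are exact.

## Known limitations

* Yaw is gyro-only; recordings much longer than the 90 s task would need
  drift handling the package deliberately omits.
* The periodogram is a raw (unwindowed, unaveraged) spectral estimate; its
  per-bin variance is high, which is acceptable for the peak/band summaries
  used here but would not be for spectral estimation per se.
* The distribution-comparison chance test inflates type I error by
  construction (see above); use `null_percentile` when calibration matters.
* The decimation step relies on the subsequent 20 Hz filter for anti-alias
  protection, mirroring the published processing order; signals with strong
  content between 50 and 150 Hz at the raw rate would alias into the band
  below 20 Hz before filtering. Consumer-wearable torso data has little
  power there.
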
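---
title: "Methods: IMU-based squat monitoring from raw signals to real-time feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU-based squat monitoring from raw signals to real-time feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

squatmon implements a complete monitoring chain for barbell squats
recorded with six body-worn 9-axis IMUs (both shanks, both thighs,
sacrum, sternum): orientation estimation and gravity removal, repetition
segmentation, a fixed 2250-item feature bank, multi-class classification
of execution technique, paired-sensor agreement statistics, and a
simulated real-time loop. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## Conventions and units

Accelerometers are stored in m/s^2 (g = 9.80665 m/s^2), gyroscopes in
rad/s, magnetometers as unit direction vectors (scale factors carry no
information for attitude). Sensor frames are right-handed as mounted;
the Earth frame is ENU with +z up, so a stationary level accelerometer
reads specific force (0, 0, +g). Orientation quaternions are scalar-first
Hamilton, mapping sensor to Earth. CSV interchange is long-format with a
YAML metadata sidecar; these are package conventions, chosen once, since
consumer IMU ecosystems standardize none of them.

## Orientation: Mahony complementary filter

Attitude is estimated per sensor by integrating the gyroscope and
correcting drift with proportional-integral feedback on the measured
gravity direction (and, in 9-axis mode, the magnetic field direction).
Defaults are kp = 1 s^-1 and ki = 0.3 s^-2, the usual range in the
complementary-filter literature; both are exposed. Three numerical
choices matter in practice:

* **Startup.** The initial attitude comes from the mean accelerometer
  direction over the first 0.5 s (roll/pitch, yaw zero). For the first
  2 s the proportional gain is raised tenfold with the integrator frozen,
  so the estimate locks onto the measurements quickly; at nominal gains a
  large initial error needs tens of seconds to decay, which would eat the
  5 s warm-up the rest of the pipeline assumes.
* **Gyro-bias capture.** The monitoring protocol starts with the subject
  standing still, so the mean gyroscope reading over the first 2 s is
  subtracted as the constant bias (standard IMU startup calibration,
  `bias_capture_s`, set 0 to disable). The integral term then only has
  to track residual drift; left alone it absorbs a 0.02 rad/s bias in
  roughly 15 s, far too slow.
* **Anti-windup.** The integral state is clamped per component (0.1) and
  frozen while the innovation exceeds 0.3 rad (conditional integration);
  without this the transient after startup winds the integrator up and
  convergence rings for many seconds.

The magnetometer only stabilizes yaw. Gravity removal needs roll/pitch
alone, so 6-axis mode is a first-class configuration (relevant where the
local magnetic field is unusable, e.g. indoors near steel or aboard a
spacecraft), and the two modes agree on gravity-free acceleration in
magnetically clean static cases.

## Gravity removal ("0g" signals)

Each specific-force sample is rotated to the Earth frame, (0, 0, g) is
subtracted, and the remainder is rotated back to the sensor frame. With
an exact attitude this is exact to machine precision (a tested
invariant over random orientations). With estimated attitudes the
residual is bounded by g times the tilt error: the acceptance checks ask
for < 0.02 g RMS on static data and < 0.05 g RMS against the simulator's
analytic gravity-free acceleration on noise-free squat kinematics, after
the 5 s warm-up. The preprocessing chain (20 Hz 6th-order zero-phase
Butterworth on all channels, then orientation, then gravity removal)
yields the 36-signal dataset: per sensor, 3 gravity-free acceleration
channels and 3 angular-velocity channels. Gyroscope channels stay in the
sensor frame; no transformed frame is defined for them.

The 20 Hz stage's order is not dictated by anything physical; 6th order
was chosen to mirror the 2 Hz stage. Offline paths filter zero-phase
(forward-backward); the real-time path uses the same filters causally,
single-pass, because zero-phase filtering is impossible online.

## Repetition segmentation

The driver signal is the Earth-frame vertical gravity-free acceleration
of the sacrum - the site that best reflects whole-body vertical
oscillation - additionally smoothed at 2 Hz. During one squat the driver
traces a W: a braking valley during the descent, a strong positive push
peak at the bottom, a second valley as the ascent brakes, and a
near-zero bump at standing. A repetition is defined as an upward-push
peak paired with its *nearest preceding* valley; boundaries are the zero
crossing before that valley and the zero crossing after the peak.
Nearest-preceding pairing is deliberately tie-free: the two braking
valleys of a cycle have nearly equal depth, and any rule that keeps "the
deeper valley" flips between noise realizations, moving a boundary by a
large fraction of a period.

Detection parameters (all configurable): prominence at least 0.5 x the
driver's IQR, same-kind extrema at least 1 s apart, and a
sign-consistency band - peaks must rise above max(zero_band, 0.25 x IQR)
and valleys below its negative - which removes the standing bump, whose
prominence alone would pass. When no sign change exists near an extremum
the boundary falls back to the nearest sample inside the zero band
(0.05 m/s^2), then to the midpoint toward the adjacent extremum, so
degenerate inputs never abort. Samples inside the 5 s orientation
warm-up are ignored; boundary-incomplete cycles at the edges are
dropped.

## Feature bank: 375 per sensor, 2250 per repetition

Per sensor, the derived signals are the gravity-free acceleration, the
angular velocity, and their jerks (first differences scaled by the rate),
each per axis and as Euclidean magnitudes; spectra are one-sided FFT
magnitudes. The registry pairs:

* nine statistics in both domains - mean, SD, MAD, max, min, SMA,
  energy (mean square), IQR, entropy;
* time-domain only: 4th-order Burg autoregressive coefficients per axis
  and Pearson correlations of the axis pairs;
* frequency-domain only: index of the spectral maximum (maxInds),
  power-weighted mean frequency, and skewness/kurtosis of the spectral
  magnitude distribution.

Four time-domain triaxial signals with their four magnitudes, three
frequency-domain triaxial signals (acceleration, gyro, acceleration
jerk - the gyro-jerk spectrum is omitted, following the convention of
the classic activity-recognition feature sets this list mirrors) with
all four magnitude spectra give exactly 375 features per sensor and
2250 per repetition. The registry ships as a manifest (per-sensor
template in `inst/extdata`, full version via `write_feature_manifest()`),
and the emitted row is checked against it name by name.

Numerical choices: time-domain statistics are computed on the
2 Hz-smoothed signals, where squat kinematics live; spectral statistics
on the 20 Hz signals, which still carry a spectrum (a 2 Hz-filtered
signal has nearly none). Time-domain entropy uses a 16-bin histogram on
the segment's own range; spectral entropy is normalized power entropy.
Segments are never resampled to a common length - every statistic is
length-invariant by construction (means, not sums) - because repetition
durations genuinely vary. Non-finite features (degenerate spectra of
constant windows, undefined correlations) are zero-filled and counted.
AR order 4 follows the activity-recognition convention.

## Scaling, feature selection, and classifiers

Scaling is robust - (x - median) / IQR - fitted on training rows only;
constant features get scale 1 and a flag. Recursive feature elimination
ranks features by squared weight of a linear maximal-margin classifier
(summed over the one-vs-one subproblems) and removes 5% of the remaining
features per round; with a sweep list the candidate count maximizing
stratified CV accuracy wins. The default pipeline target is 100 of 2250
on the synthetic benchmark, where 300 repetitions cannot support
hundreds of columns; the selector accepts any target, including the
769-column reduction reported for the original human dataset.

Five families are compared under identical stratified 70/30 splits and
stratified 10-fold cross-validation: decision tree (Gini, effectively
unlimited depth), random forest (100 trees), KNN (k = 5, Euclidean,
with vote-fraction posteriors computed in-package because no installed
implementation returns the full 6-class vote vector), SVM (RBF, C = 1;
the underlying library couples one-vs-one rather than one-vs-rest), and
a single-hidden-layer perceptron with softmax output via nnet. Two MLP
choices are the package's own: nnet offers a logistic hidden layer (no
ReLU), and the default size is 30 units with 200 optimizer iterations -
nnet's dense BFGS makes 100 units prohibitively slow on one CPU while
changing nothing measurable at these problem sizes. All hyperparameters
are exposed.

Metrics are macro-averaged over the six classes from a confusion matrix
with rows = actual and columns = predicted: accuracy, specificity,
sensitivity, precision, each the mean of the per-class one-vs-rest
value; classes with an empty denominator are excluded from that metric's
mean with a warning, so degenerate matrices never produce non-finite
output. Note that macro accuracy of a constant predictor on balanced
six-class data is ~0.72, not 1/6 - chance level should be judged on the
confusion diagonal.

Mixed errors: `predict_report()` returns the full probability vector and
flags every error class at or above 0.25 (configurable), so a repetition
that is simultaneously "knees over toes" and "raised heels" yields both
advices.

## Paired-sensor agreement

Two co-located recordings are aligned by the integer lag maximizing
normalized cross-correlation of the driver channel (weak peaks fall back
to zero lag with a warning), then compared per channel by Pearson R and
by Welch magnitude squared coherence (2 s Hann windows, 50% overlap,
summarized over 0.1-5 Hz, where squat energy lies; at least two windows
are required, since single-window coherence is identically 1). Family
summaries average over sensors and axes, excluding channels whose SD is
below 10% of the family's most active channel - a channel that carries
no movement, only noise, has no agreement information - and weight the
coherence summary by auto-power, because near-periodic movement has a
line spectrum and an unweighted band mean is diluted by empty
inter-harmonic bins. The 0.5 MSC threshold is reported as a flag, not
enforced.

## The squat simulator

The generator is a planar kinematic chain - foot-fixed ankle, shank,
thigh, trunk, with one frontal-plane degree of freedom for valgus - and
is the package's test substrate, not a biomechanical model. Joint angles
follow raised-cosine cycles (peak knee flexion 1.4 rad, trunk pitch
0.35 rad, ankle dorsiflexion 0.35 rad, 3 s period; segment lengths
0.43/0.42/0.50 m; 6 s stationary lead-in covering the warm-up, 2 s
tail). Error classes perturb the base pattern proportionally to a
severity in [0, 1]: extra trunk pitch (RB, 0.5 rad), extra dorsiflexion
(KOT, 0.3 rad), frontal-plane knee oscillation (VK, 0.25 rad), shank
pitch offset plus a heel rise at the bottom (RH, 0.2 rad / 0.02 m), and
depth scaled by 1 - 0.6 x severity (SH). The heel-rise excursion is the
chain-origin displacement, deliberately smaller than a physical heel
raise (which mostly pivots the foot): larger values inject enough
bottom-of-cycle acceleration to split the push peak and break the
one-cycle-per-repetition contract.

Sensors are rendered exactly: accelerometer = (kinematic acceleration
minus gravity) rotated into the sensor frame, gyroscope from the
quaternion track, magnetometer a fixed dipping field direction; white
noise per channel (defaults 0.1 m/s^2, 0.02 rad/s, 0.005) and a constant
per-trial gyro bias (SD 0.02 rad/s) are added under the configured seed,
values typical of consumer MEMS parts during movement. Ground truth
carries the exact orientations, the analytic gravity-free accelerations,
and repetition boundaries obtained by applying the documented boundary
rule to the *analytic* sacrum vertical acceleration after the same 2 Hz
smoothing - the truth path never touches rendered IMU data, the Mahony
filter, or gravity removal, so comparing detected against true
boundaries isolates noise and estimation error.

The benchmark emulates the study design: 6 classes x 5 subjects x 10
repetitions, one trial per subject per class, with 10% multiplicative
jitter on depth, period, trunk lean and dorsiflexion per trial. Severity
is fixed at 1.0: the benchmark poses the recovery question "are the six
canonical patterns distinguishable through the full pipeline", not a
psychometric difficulty sweep.

**What passing does and does not show.** The simulator produces smooth,
exactly periodic kinematics with stationary Gaussian noise. It contains
no soft-tissue artifact, no sensor mounting slip, no fatigue drift, no
inter-repetition tempo variation within a trial, no magnetic
disturbance, and its error classes are single-cause by construction.
End-to-end accuracy near 1.0 on this benchmark therefore validates the
*plumbing* - signal conventions, orientation and gravity removal,
segmentation, feature computation, selection and model code - and not
classification difficulty on real athletes, where published accuracies
in the high-80s to high-90s are the realistic range.

## Real-time monitoring

The online path reuses the batch components causally: single-pass
filters, the (inherently causal) Mahony update, and an online segmenter
that confirms extrema by turning-point detection (reversal by the
prominence threshold, computed over a trailing 10 s window), pairs a
push peak with its nearest preceding valley, and closes the repetition
at the trailing zero crossing plus a 0.25 s guard. The guard trades a
quarter second of latency for boundary stability. No event's feature
window extends past the samples streamed at emission time, and
causal-versus-zero-phase filtering may flip borderline windows, so
online labels are only required to agree with the batch pipeline on at
least 80% of repetitions (a tested property). Problem sizes throughout
the test suite - trials of 5-20 repetitions at 100 Hz, a 300-repetition
benchmark - match the scale of the original study design.

## Known limitations

* The simulator's sagittal-chain geometry ignores pelvis constraint
  during valgus and models the barbell load kinematically not
  kinetically; load magnitude does not enter the signals.
* Axis conventions of physical sensor mountings are documentation
  (`sensor_layout()`), not enforced geometry; real deployments must
  align axes or calibrate.
* KNN and SVM posteriors are vote fractions and pairwise-coupled
  probabilities respectively, not calibrated probabilities; the 0.25
  mixed-error threshold is a design constant, not a learned one.
* libsvm's probability calibration draws from a C RNG that cannot be
  re-seeded from R within a session; predicted labels are deterministic,
  SVM probability values may vary in the last digits between fits.
* The optional repetition outlier screen (non-finite-feature fraction,
  duration outside 1-10 s) is disabled by default and is an artifact
  decision: the row reduction it emulates in the original dataset is
  unexplained there, and no rule is guessed.
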
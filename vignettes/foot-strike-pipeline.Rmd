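---
title: "Foot strike estimation from two-sensor insoles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foot strike estimation from two-sensor insoles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(footstrike)
```

## The problem

The foot strike angle (FSA) is the sagittal-plane angle of the foot at
initial ground contact: positive angles mean a heel-first (rear-foot)
landing, negative angles a toe-first (fore-foot) landing. The discrete foot
strike pattern (FSP) buckets the angle with the Altman–Davis cut-offs:
fore foot below −1.6°, rear foot above 8.0°, mid foot in between (both
boundaries belong to mid foot). Measuring FSA directly needs motion
capture; a two-sensor pressure insole records only a fore and an aft
vertical force channel at 100 Hz. This package implements the inferential
chain from those two channels to FSA and FSP, and the simulator that stands
in for the original recordings, which are not publicly available.

## Event detection

Initial contact is the first frame whose total-force loading rate (backward
first difference times the sampling rate) exceeds +1500 N/s; toe off is the
last frame below −1500 N/s. Choices worth stating:

* **Total force, not per-sensor.** The event definition could be read
  per-sensor; we threshold the summed channel, the conservative reading
  that is robust to a silent sensor (a pure fore-foot landing barely moves
  the aft channel).
* **Frame resolution.** Events are single frames; no sub-frame
  interpolation, matching the 100 Hz frame-wise definition. All timing
  quantities inherit a one-frame (1%–5% of stance) quantization.
* **Last crossing at toe off.** Using the last negative crossing guards
  against mid-stance unloading dips in bouncy strides.

## The ten predictors

Over the detected stance (and its first third, `IC` to
`IC + round((TO − IC)/3)`, inclusive — frame rounding stated explicitly):
fore/aft impulse shares of the total impulse (trapezoidal integration);
fore/aft peak-force shares of the peak total force; fore/aft peak
loading-rate (RFD) shares; and the natural log of the stance-percent
(IC = 0%, TO = 100%) at which each sensor's loading rate peaks.

Conventions that matter when plugging numbers into the published
regression:

* **Fractions, not percent, for the ratio predictors.** The published
  coefficient vector only reproduces the class-mean angles when the five
  ratio predictors are fractions in [0, 1] and the two log-timing
  predictors are logs of a 0–100 percent scale. `scripts/acceptance.R`
  verifies this by evaluating the regression at the class-mean profiles.
* **RFD ratios may exceed one.** Each sensor's rate is maximized at its own
  frame; a sensor can load while the other unloads, so the sensor maximum
  can exceed the total-force maximum. Impulse and peak-force shares cannot.
* **Ties and degeneracies.** The first frame wins RFD ties; a sensor whose
  rate is never positive gets `NA` log-timing with a warning; a rate peak
  exactly at IC (log of zero percent) is an error rather than a silent
  `-Inf`.
* **Normality screen.** Standardized skewness and excess kurtosis (moment
  over its standard error, SPSS `type = 2` definitions) are compared to
  2.58; that threshold is the two-sided 1% z critical value, which is why
  the standardized rather than raw statistic is assumed.

## Models

**Published regression.** A fixed-coefficient affine map from seven of the
ten predictors to FSA (intercept −89.2; see `published_mr_model()`). It is
data, not something this package fits.

**Stepwise regression** (`fit_stepwise_mr()`). SPSS-style forward entry at
partial-F p ≤ 0.05 with backward removal at p ≥ 0.10. The removal
threshold printed in the source material (0.0100) would make removal
stricter than entry, which is inconsistent for probabilities; we read it as
0.10. AIC and BIC use the Gaussian forms with the constant dropped,
`n·log(RSS/n) + 2(k+1)` and `n·log(RSS/n) + (k+1)·log(n)`. Candidates
perfectly collinear with the current model (the two impulse-ratio pairs sum
to one by construction) are skipped with a warning.

**Conditional-inference tree** (`fit_strike_tree()`). At each node every
candidate predictor is tested for association with the response using the
closed-form permutation moments of its linear statistic —
`z = sqrt(n−1)·|r|` against a normal reference for a numeric response,
`(n−1)·η²` against χ²(K−1) for a class response — with Bonferroni
adjustment across the ten candidates. The node splits on the most
significant predictor only if its adjusted p ≤ α = 0.01 (the
minimum-splitting-criterion 0.99 convention), at the cut maximizing the
standardized two-sample statistic; splitting also stops at the depth cap
(8 for angle prediction, 6 for classification), below 20 cases per node, or
below 7 cases per child. This is a faithful simplification of the
conditional-inference framework, not a bit-exact clone of any reference
implementation; asymptotic rather than resampled reference distributions
are the framework's own default.

**Random forest** (`fit_strike_forest()`). 500 trees via the
`randomForest` package; the per-split candidate count is tuned over
{2, 3, 4, 5} by 5-fold cross-validation (lowest RMSE for prediction,
highest accuracy for classification, ties to the smaller value), then the
forest is refit on all training rows. Out-of-bag error and
impurity-decrease importance are reported; importance has no numeric
target here and is exposed for inspection (`tidy()`, `autoplot()`).

**Classification route.** Models that output an angle are classified by
thresholding the predicted angle through the same cut-offs used for truth
labelling — deliberately no recalibration, so classification errors reflect
angle errors near the boundaries.

## Evaluation

MSE, RMSE, MAE and MAPE (a unitless fraction; records with a true angle of
exactly 0° are excluded from MAPE only, with a logged count — a degree
label on a MAPE is treated as a typesetting artifact). Bland–Altman bias is
the mean of true − predicted, limits are bias ± 1.96 sample standard
deviations (n−1 denominator), and "maximum precision" is the width between
the limits. Confusion matrices use the fixed order RF, MF, FF (rows =
true); accuracy, recall and precision are percentages; precision of a
never-estimated class is `NA`, and report formatting rounds half away from
zero to one decimal (banker's rounding would disagree with the published
tables in edge cases).

## The simulator

No waveform-level statistics (peak forces in Newtons, stance durations)
were available to calibrate against — only the derived feature ratios per
class. The generator therefore fixes realistic envelope conditions as its
own design choices: 100 Hz sampling, stance durations uniform on
0.20–0.35 s, peak total force uniform on 1500–2500 N (about 2–3 body
weights), 80 ms zero-force padding on both sides, and 1% heteroscedastic
sensor noise (`sd = noise_sd · peak · sqrt(f/peak)`, so an unloaded sensor
stays quiet and the zero-force padding cannot trip the 1500 N/s event
threshold).

Each sensor is a sum of raised-cosine pulses over the stance: the aft
sensor a small heel-touch shoulder plus a later roll-on pulse, the fore
sensor an early impact bump plus a broad propulsive pulse whose fall ends
with a quarter-cosine (toe off is an abrupt unloading, which also keeps the
detected toe-off frame within two frames of the generated stance end).
Pulse amplitudes and timings are linear in a bounded rearfoot-ness score
`u = plogis((fsa − 6)/8)`, capped at 0.97 because load sharing saturates
for extreme heel-first contacts. The maps were calibrated once, before the
test suite was frozen, so that noiseless extracted features at +25° sit
inside the rear-foot mean ± 2 SD envelope of the published class profiles,
the four aft-side shares are nondecreasing in the generating angle over
−25° to +40° (checked on a 5° grid across the full duration range), and
the class-mean angles reproduce the published FF/MF/RF ordering of all
eight ratio features.

**What the simulator does not emulate.** Biomechanically validated waveform
shapes (no anti-pulse dynamics, no shoe–midsole filtering); between-runner
variability (feature scatter comes only from stance duration, peak force
and sensor noise, so the feature–angle map is much cleaner than real data —
trainable models reach held-out errors well below those achievable on real
steps, and passing the end-to-end tests demonstrates pipeline correctness,
not field accuracy); the log-timing predictors carry little systematic
signal (their class separation in real data is weak, and here the fore
timing is nearly constant by construction); and frame-resolution event
jitter produces isolated ≈0.01 wiggles in the first-third impulse share at
1° angle resolution for some stance durations — real, documented, and below
any class contrast of interest.

## Problem sizes in the test suite

The suite exercises the statistical claims at sizes chosen to keep
Monte-Carlo error well below the asserted tolerances: 10,000 draws for
distributional moments and Bland–Altman coverage; n = 5000 with 5.1° noise
for recovering the published coefficients within ±10% (the smallest
coefficient, 1.8, has a standard error near 0.07 there); n = 2000 balanced
simulated steps for the forest-versus-tree comparison at 500 trees; and
1,500 balanced steps for the full-pipeline classification check. The
null-behavior test of stepwise entry asserts the closed-form familywise
rate for min-p selection, `P(empty) = 0.95^10 ≈ 0.60`, within Monte-Carlo
tolerance.

## Known limitations

* Events are frame-resolution; with 20–35 samples per stance, timing
  features are coarsely quantized at 100 Hz.
* The conditional-inference tree uses asymptotic test distributions;
  at very small node sizes (near the 20-case minimum) the significance
  gate is approximate.
* The simulator's feature–angle map is deterministic given (angle,
  duration, peak, noise); it cannot be used to benchmark absolute accuracy
  against motion capture, only to validate the pipeline's logic and the
  relative behavior of the models.
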
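---
title: "Cuffless blood pressure from ECG and PPG: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood pressure from ECG and PPG: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufflessbp)
```

## The problem

Cuffless blood-pressure estimation couples two synchronously recorded
signals — a single-lead ECG and a finger photoplethysmogram (PPG) — through
the physiology of pulse-wave propagation: higher arterial pressure stiffens
the vessel wall, the pressure wave travels faster, and the pulse transit
time (PTT, the delay from the ECG R peak to the arrival of the pulse wave
at the periphery) shortens. A linear regression

$$\mathrm{BP} = A_0 + A_1 F_1 + A_2 F_2 + \dots + A_n F_n$$

maps PTT together with morphological features of the pulse wave (landmark
timings, log-amplitudes, augmentation and perfusion indices, spectral
summaries) to systolic and diastolic pressure, calibrated against cuff
readings. The validation layer asks the clinical question: how well do the
cuffless estimates agree with the cuff reference, and would disagreements
matter at the bedside?

Clinical recordings of this kind are not publicly deposited, so the package
is organised around a synthetic cohort generator with exact ground truth.
Every downstream stage — fiducial detection, feature extraction,
calibration, agreement analysis — is tested against quantities the
generator knows exactly.

## The synthetic beat model

One cardiac cycle of PPG is modelled as a DC level plus the sum of three
positive Gaussian components: the systolic ejection wave, the reflected
(backward) systolic wave returning from the periphery, and the diastolic
wave. This mirrors the forward/backward decomposition view of pulse-wave
analysis while keeping every landmark analytically accessible:

* **B1** — the foot of the wave (see below),
* **B0** — the maximum-upstroke point, the maximum of the first derivative,
* **SEP** — the systolic ejection peak,
* **DER3** — first positive peak of the third derivative after B1,
* **SEPMAX** — first inflection (second-derivative zero crossing) after SEP,
* **SRP** — the reflected systolic peak,
* **DP** — the diastolic peak, which a wave need not possess,
* **End** — the end of the cycle.

The ECG is an R-dominant template (narrow Gaussian, 8 ms width, 1 mV) on a
flat baseline: only R timing feeds the method, so PQRST morphology would
add nothing testable.

### Where exactly is the foot?

The generator places each beat so that the **intersecting-tangent foot** of
the continuous noise-free waveform falls exactly at R-peak time + PTT. The
tangent construction (tangent through the maximum-upstroke point,
intersected with the pre-upstroke baseline) is the standard operational
definition of the pulse foot, and it is what the detector computes. Tying
the generator's truth to the same definition makes "foot at R + PTT within
one sample" and "detector recovers the foot" simultaneously satisfiable; an
alternative definition (first sample of support) would disagree with any
tangent-based detector by roughly twice the ejection width — tens of
milliseconds — for purely geometric reasons.

Ground-truth landmark positions are computed from the continuous model, not
from samples: B0 by maximizing the analytic derivative, SEP/SRP/DP as the
downward zero-crossings of the derivative attributed to the nearest
component center. A reflected or diastolic component whose bump is
swallowed by its neighbour's flank leaves no zero crossing; that landmark
is then recorded as genuinely absent rather than forced — the same policy
the detector follows, since diastolic peaks routinely vanish in stiffer,
older vasculature.

## The cohort model

`cohort_params()` encodes the study conditions:

* SBP truncated-normal with mean 125, sd 18.8, range 90–175 mmHg; DBP mean
  76, sd 12.4, range 54–105 mmHg. The stated moments are the moments of the
  *truncated* law: parent parameters are solved by moment matching, because
  the truncation here is asymmetric and would otherwise inflate the
  realized mean by about a tenth of an sd. SBP is drawn from its truncated
  marginal; DBP conditionally (latent correlation 0.6), redrawing only the
  conditional component when a draw leaves the range or the pulse pressure
  falls under 15 mmHg — this keeps the SBP marginal exact.
* PTT coupling: true PTT (ms) = 400 − 1.5·SBP + subject jitter (sd 4 ms).
  The physiological literature supports a decreasing, approximately affine
  relation over clinical ranges; the specific coefficients were chosen once
  to land PTT in the familiar 140–270 ms window across the SBP range.
* Reflected-wave delay: delay (s) = 0.27 − 0.001·DBP + jitter (sd 3 ms),
  giving diastolic pressure its own observable channel in the waveform.
* Heart rate: truncated normal, 64 ± 6 bpm in 50–78 — a resting hypertensive
  outpatient population; the upper bound also keeps the full three-component
  wave inside the shortest cardiac cycle.
* Cuff protocol: three readings with i.i.d. Gaussian error (default sd
  3 mmHg, a mid-range figure for oscillometric devices; no error model is
  established for this design), averaged to one reference pair — so the
  reference itself carries sd 3/√3 ≈ 1.7 mmHg of noise, a floor no
  estimator can beat.
* Channel noise: additive white noise, default sd 0.02 (PPG units, ~2% of
  pulse amplitude) and 0.02 mV (ECG).

All randomness flows from one integer seed through a single RNG stream in
subject order (the train/test split uses a fixed-offset substream), so a
cohort is reproducible bit for bit.

What the generator does **not** emulate: motion artifacts beyond additive
noise, respiratory modulation of baseline and amplitude, arrhythmia,
beat-to-beat BP variability, sensor saturation, and drift between the cuff
session and the recording. Passing tests therefore demonstrate correctness
of the algorithms under the stated model, not clinical performance; the
agreement statistics the pipeline reaches on synthetic cohorts are upper
bounds that real data would erode.

## Signal processing choices

**R peaks** are found Pan-Tompkins style: zero-phase 5–25 Hz Butterworth
bandpass, differentiation, squaring, 120 ms moving-window integration, a
threshold placed between the noise floor (median of the energy envelope)
and the QRS level (99.5th percentile), and peak refinement on the
bandpassed signal with a 250 ms refractory period. The bandpass stage is
load-bearing: differentiating raw wideband noise at 1 kHz swamps the QRS
energy entirely.

**Segmentation** is R-to-R; segments tile the record with no gaps and the
partial cycles at both ends are dropped.

**Quality gating** resamples every beat's PPG to 200 samples, builds the
record's median template, and scores each beat by its correlation with the
template, clamped to [0, 1]; default acceptance threshold 0.9. This mirrors
the per-cardiocycle quality comparison that ambulatory devices apply before
analysis. The gate is monotone in the threshold by construction.

**Derivatives** are taken with Savitzky–Golay filters (polynomial order 3,
21 ms window; order 5, 31 ms for the third derivative) rather than the
more obvious zero-phase low-pass + finite differences: SG filtering has no
edge transient on short single-beat segments — where a forward-backward IIR
filter corrupts precisely the pre-upstroke region the foot estimate needs —
and yields smoothed derivatives of any order in one pass. Third derivatives
amplify noise; they are never computed on raw samples.

**Peak searches** (SEP, SRP, DP) require a candidate to dominate a ±20 ms
neighbourhood and exceed a prominence floor (8% of pulse amplitude above
baseline for the post-systolic peaks), which keeps residual noise ripple
from masquerading as a reflected or diastolic peak. When the reflected wave
forms no distinct maximum, its shoulder is taken at the most concave point
(second-derivative minimum) after the first inflection; when only one
post-systolic maximum exists, it is read as the diastolic peak exactly when
such a shoulder precedes it at a plausible distance, otherwise as the
reflected peak with the diastolic peak flagged absent.

**Wave decomposition** fits two positive Gaussians plus baseline by
Levenberg–Marquardt, seeded from the detected fiducials. Non-convergence or
a residual energy fraction above 10% flags the decomposition unreliable
instead of raising an error; components are reported forward-first by
center.

## Features and aggregation

Per beat: PTT (R → B1, ms); landmark times relative to B1 (ms); natural-log
amplitudes at SEP/SRP/DP over the B1 baseline (non-positive amplitudes are
flagged missing, never −∞); augmentation index = 100·amp(SRP)/amp(SEP) (one
of several conventions in use; fixed here and documented); perfusion
index = 100·AC/DC; normalized spectral band powers 0–2, 2–5, 5–10 Hz and
the spectral centroid of the beat's spectrum; beat duration and upstroke
time. Record-level features are per-feature **medians** across accepted
beats (with feature-wise missing-data exclusion, no imputation): a median
over ~60–180 beats is what makes the record-level PTT far more accurate
than any single beat. At least 10 accepted beats are required, otherwise
the record is rejected — mirroring the study-design exclusion of
poor-quality recordings.

## Calibration

Separate models are fitted for SBP and DBP. Feature selection is forward
stepwise on k-fold cross-validated squared error (folds drawn
deterministically from the seed) with a **one-standard-error admission
rule**: a candidate enters only if it improves the CV error by more than
that error's fold-to-fold standard error. Plain greedy CV admits one or two
pure-noise features routinely; the 1-SE rule drives the selected set to
empty on pure-noise targets while never hesitating over genuinely coupled
features. The final fit is OLS with coefficient standard errors and CIs;
rank deficiency is reported with the offending columns named rather than
silently aliased. Predictions are affine in the features and clamped to
[40, 260] mmHg with a warning, and models serialize to versioned JSON.
A per-subject recalibration hook (individual intercept adjustment from
repeat visits) is a natural extension and deliberately not implemented.

## Evaluation layer

Differences are everywhere oriented **predicted − reference** (cuffless
minus cuff). Bland–Altman reports bias, sd, the t-based 95% CI of the bias
and its test against zero, and limits of agreement bias ± 1.96 sd;
zero-variance differences collapse the CI onto the bias with a null p
rather than an error. Spearman correlation uses mid-rank ties. Subgroup
analysis groups subjects by their cuff reference (low: SBP < 110 and
DBP < 70; high: SBP > 140 or DBP > 90; middle otherwise) and tests zero
median error with the one-sample Wilcoxon signed-rank test — the subgroup
tables this mirrors are one-sample layouts, and a two-sample reading of the
"Mann–Whitney–Wilcoxon" naming would have no second sample to compare
against.

The zonal error grid is a Clarke-style partition of the
reference-vs-predicted scatter by relative deviation
d = |predicted − reference| / reference, with zone boundaries at **exactly
1/12, 2/12, 4/12 and 5/12** and inclusive upper edges. The fractions are
stored as rationals, not as the rounded percentages (8.3%, 16.6%, ...)
used when quoting them: for a 140 mmHg reference, 140·11/12 = 128.33
prints as 128.3, whereas a literal 0.917 multiplier would print 128.4 —
the worked boundary values are only reproducible from the exact rationals.
Boundary values are presented with half-up rounding to one decimal;
internal computation never rounds.

Hypertension (> 140/90 mmHg) and prehypertension (> 130/85 mmHg) labels
use the OR rule over both pressures, applied identically to reference and
predicted values. Sensitivity, specificity and accuracy come from the
confusion table; since a binary label has no ROC curve of its own, the AUC
is computed on a continuous exceedance score — the larger of the two
threshold-scaled exceedances of the predicted pressures — with DeLong
variance for its 95% CI. A constant score yields AUC 0.5; a single-class
reference yields null sensitivity or specificity with a warning.

## Problem sizes and reproducibility

The analysis drivers use a 200-subject cohort of 60 s records at 500 Hz
(train/evaluate split 50/50), cohort-moment checks at n = 2000, and
coverage studies of 100 replicates at n = 500 at the feature level; the
test suite uses smaller cohorts of the same structure. These sizes were
chosen as the point where every Monte-Carlo tolerance in the test suite is
comfortably resolved; the pipeline scales linearly in subjects × duration ×
sampling rate. A pipeline run writes its effective configuration beside its
outputs, and an identical seed and configuration reproduce the report JSON
byte for byte.

## Known limitations

* The generator's beat-to-beat variability is limited to RR jitter and
  white noise; quality-gate behaviour on real artifacts (motion, contact
  loss) is only exercised by constructed saturation fixtures.
* SEPMAX follows the "first inflection after SEP" reading; the alternative
  convention (inflection before the reflected peak) is the same point on
  waves with a distinct reflected peak but can differ on shoulder-type
  waves. The choice is isolated in one place in the detector.
* The feature set is a plausible superset; which spectral/time parameters
  a production device uses is not public, and the selection stage exists
  precisely to let the data decide.
* Agreement numbers obtained on synthetic cohorts characterize the
  algorithms, not any device's clinical accuracy.
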
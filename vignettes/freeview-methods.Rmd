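---
title: "Methods: calibration, saccade detection, and field mapping in freely viewing subjects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, saccade detection, and field mapping in freely viewing subjects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freeview)
```

`freeview` packages the analysis chain used to prepare oculomotor
electrophysiology experiments in subjects that view a screen freely rather
than performing rewarded fixation trials: calibrating the eye tracker from
spontaneous fixation clusters, detecting saccades by velocity and
acceleration thresholds, and mapping visual receptive fields (RFs) and
saccadic motor fields (MFs) by reverse correlation. This vignette explains
each model, the parameters that matter, the design decisions that were
genuinely open, and what the bundled simulator does and does not capture.

## Gaze signal model and fixation detection

The raw tracker signal is a uniformly sampled pair (x, y) in volts; after
calibration the same container carries degrees. A unit tag travels with
every trace, and kinematic operations refuse uncalibrated input — this
catches the most common pipeline mistake (differentiating volts) at the
type level.

Smoothing uses a centered moving average with a 20 ms window: the window
length in samples is the odd count nearest to `window_ms * rate_hz / 1000`
(21 samples at 1 kHz, 3 at 120 Hz), and edge windows shrink rather than
trim so output length equals input length and event alignment by index is
preserved. Velocities come from central differences (one-sided at the
ends), which are unbiased to second order on a uniform grid; angular speed
is the Euclidean norm of the component velocities, and acceleration is the
central difference of speed. Mixed sampling rates (a 120 Hz video tracker
vs. a 1 kHz digitized channel) are handled natively by rate-aware window
and derivative computations — no resampling, so threshold-crossing times
are never distorted by interpolation.

"Stable gaze" is operationalized as a dispersion criterion (the I-DT
family): a maximal run of samples is a fixation when the range of x and
the range of y each stay within a threshold and the run lasts at least
500 ms. A velocity-bounded definition would be the natural alternative;
dispersion was chosen because it matches the 1–2° cluster widths that
motivate the calibration design, needs no calibrated velocities (it works
directly on volts), and is self-checkable — every returned fixation can be
re-verified against its defining predicate on the raw samples, which the
test suite does. The default threshold is 1.5° (0.3 V at a nominal
5 deg/V tracker scale). The 500 ms minimum also serves the calibration:
shorter fixations are mostly saccadic corrections and random glances, and
excluding them is what makes the fixation clusters conspicuous.

The detector runs a single left-to-right sweep with monotonic-deque
running extrema, so it is linear-time and deterministic: fixations are
emitted greedily, disjoint, and maximal given the preceding detections.

## Calibration from fixation clusters

During calibration a salient flickering spot (1°, 30 Hz) is displayed for
2 minutes at each of five locations: center and ±7° on each axis. The
subject is not required to do anything; enough spontaneous fixations land
on the stimulus to form one cluster per location. Fixations are assigned
to an epoch only when their whole duration lies inside it; boundary
stragglers stay unlabeled.

Cluster centers are extracted per axis by fitting the amplitude-form
Gaussian `a·exp(−((x−b)/c)²)` to a histogram of the fixation coordinates
(Freedman–Diaconis bin width, floor of 8 bins, grid extended half a bin so
extreme values sit at bin centers). A histogram fit rather than a
raw-sample likelihood is deliberate: the uniform background of
off-stimulus fixations contributes a low pedestal that a fitted amplitude
tolerates, whereas a sample mean or ML Gaussian would be dragged toward
the screen center. Initial values are a = tallest bin, b = sample mean,
c = SD·√2, with b constrained to the data range. Two failure modes fall
back to robust moments (b = median, c = 1.4826·MAD·√2): optimizer
non-convergence (rmse reported as NaN) and a fitted width exceeding the
whole data span, which means the optimizer settled on a flat line rather
than a cluster (a genuine Gaussian sample has c ≈ 0.25·span); in the
latter case the robust curve's rmse is still reported so that, e.g.,
bimodal input is flagged by a large residual rather than silently
accepted.

With five collinear-in-pairs stimulus locations there are three distinct
degrees per axis, so the gain and offset are estimated by an ordinary
least-squares line through all (raw center → stimulus degree) pairs rather
than any two-point solution; the axes are calibrated independently (no
rotation or shear terms — the tracker's axes are assumed aligned with the
screen's). Cluster widths map to degrees through |gain|, and residuals are
the distances between calibrated centers and the true stimulus locations.
Later-session drift is handled by `offset_recalibrate()`, which shifts
only the offsets by the displacement between fixations on a known fixation
point and that point's location, keeping the gains.

## Saccade detection

Detection follows printed threshold rules: speed above 100 deg/s marks a
candidate; the candidate survives if the absolute acceleration within it
exceeds 5000 deg/s²; the onset is the first sample in the 100 ms window
before the peak-velocity sample where speed exceeds 20 deg/s. Three gaps
had to be closed:

* **Offset rule.** Undefined by the thresholds above; the package mirrors
  the onset rule — first sample after the peak where speed falls below
  20 deg/s, capped at 100 ms past the peak.
* **Signed vs. absolute acceleration.** The absolute maximum is used, so
  the braking phase of a saccade also confirms it.
* **Pathological onsets.** If no pre-peak sample exceeds 20 deg/s (possible
  only in contrived input), the window start is used and the saccade is
  flagged, preserving a total ordering.

Candidates whose onsets fall within 50 ms of each other are merged, which
suppresses double detection of dynamic overshoots; the gap is
configurable. Start and end positions are read from the smoothed trace at
the onset and offset samples, giving amplitude and direction
(0° = rightward, counterclockwise positive).

For motor-field work, saccades are binned into six 60° direction bins
(edges at 0° by default, rotation configurable — only the width is
dictated by the method) and three amplitude bands. The bands are half-open
— [0,5), [5,10), [10,∞) — so that every saccade lands in exactly one bin;
the boundary values 5 and 10 go up, a convention chosen because "5–10"
reads as inclusive on the left while ">10" claims the point 10's
right-neighborhood, and one of the two had to own each boundary.

## Receptive fields by reverse correlation

The stimulus is a 2° patch flashed 50 ms per cell over a 6×6 grid spanning
22×22°. Cell centers divide the extent into six equal strips per axis; the
patch being smaller than the ≈3.67° cell pitch is a display property that
does not enter the analysis geometry. For each cell,

C(t′) = (1/n) · (1000/Δt) · Σ over the cell's n presentations of the
spike count in [onset + t′, onset + t′ + Δt),

with Δt = 50 ms the presentation window — the only reading of the window
term under which C has units of Hz. Windows are closed-open so each spike
is counted in exactly one adjacent window; cells with fewer than 5
presentations are undefined rather than noisy. The RF center is the
centroid of the defined cells at or above halfway from the baseline
(median of defined cells) to the peak; a flat map raises an error rather
than returning a fabricated center.

The response latency t′ is subtracted before correlating. Its estimation
is not specified by the thresholds above, so the package defaults to a
fixed 40 ms — a typical collicular visual latency — and offers a
data-driven alternative: a 1 ms grid search over 0–100 ms maximizing the
peak z-score of the map, returning the default with a flag when no shift
produces structure (best z below 3.5; stimulus-independent spiking
reliably trips this, while even a modest embedded response clears it).

## Motor fields and the visuomotor index

Spikes within ±50 ms of each saccade onset are tallied into the polar
binning; each bin's rate is total spikes / (saccade count × 0.1 s). Bins
with fewer than `min_count` saccades are undefined — 3 by default, suited
to short sessions where conditions hold under ten saccades; for long
free-viewing blocks (hundreds of saccades) a higher floor such as 20 is
appropriate, because with many bins a single low-count bin will
occasionally show a large spurious rate and, being compared against
half-of-maximum, can hijack the map's peak region. Windows of saccades
closer than 100 ms may double-count spikes; this is the plain reading of a
fixed peri-saccadic window, and an exclusion flag was judged not worth the
bookkeeping for inter-saccade intervals that rarely fall below 200 ms.
Preferred-bin ties resolve deterministically (lower amplitude band, then
lower direction index).

The visuomotor index divides the mean rate of RF cells at or above half
the peak by the mean rate of defined MF bins at or above half the peak
bin. A zero motor rate yields an explicitly undefined ratio, never
infinity. One analysis-design point matters in practice: motor fields must
be computed from free-viewing saccades only. Saccades made during the
RF-mapping block carry patch-evoked visual spikes inside the ±50 ms
window, and for strongly visual channels this contaminates the motor map
enough to corrupt the index. The mapping function itself is block-agnostic;
the pipeline and tests restrict the saccade table by block.

## The synthetic session

`simulate_session()` emulates the study conditions end to end:

* **Behavior.** Alternating fixations and saccades. Fixation durations are
  log-normal (median 700 ms, log-SD 0.4, truncated below 200 ms). During a
  calibration epoch a fixation targets the active stimulus with
  probability `p_attend` = 0.6 plus Gaussian landing scatter (SD 1.5°,
  matching the 1–2° cluster widths the calibration is designed around);
  otherwise the target is uniform over the 56×31° screen. During RF
  mapping the attended target is the central fixation point; during free
  viewing all targets are uniform.
* **Kinematics.** Saccades follow a minimum-jerk profile with a linear
  main sequence D = 20 + 2·A ms. Minimum jerk was chosen because its peak
  velocity is analytic (1.875·A/D), which gives closed-form oracles: an
  amplitude-2° saccade peaks at 156 deg/s, safely above the 100 deg/s
  detection threshold, and the whole main sequence is recoverable from the
  trace.
* **Tracker.** Degrees map to volts by inverting a per-axis affine model
  (defaults: gain 5 deg/V, offsets 2 and −1°) plus white voltage noise
  (SD 0.05 V); a small positional noise (SD 0.02°) is added in degrees.
* **Spiking.** Per channel, an inhomogeneous Poisson process by thinning —
  exact and seedable. The rate is baseline + a visual term while a patch
  is on (Gaussian RF evaluated at the patch center, shifted by the
  latency) + a motor term (temporal Gaussian bump at each saccade onset,
  scaled by Gaussian tuning of the saccade vector around the preferred
  direction and amplitude). The default channel is a vigorous visuomotor
  neuron: baseline 10 Hz, RF peak 100 Hz at (5.5, 5.5)° with σ = 2°,
  latency 40 ms, burst 200 Hz (σ = 15 ms) preferring 33° direction and
  7.5° amplitude.

Fixed seed means byte-identical bundles; the RNG is seeded once per
session and every stage draws from the same stream.

**The layered array.** `layered_config()` emulates a perpendicular
16-channel penetration of the superior colliculus: all channels share the
RF center and preferred vector, while the visual peak falls and the motor
burst rises geometrically with depth (400 → 8 Hz against 8 → 400 Hz,
baseline 5 Hz). The spans were chosen by a power argument: the per-channel
log-step of the expected visuomotor ratio (≈0.4) must exceed roughly three
times the sampling error of the half-max estimators, which at 80
repetitions per grid cell and 900 s of free viewing is a few percent.
Tuning is deliberately broad (RF σ 3.5°, direction σ 45°, amplitude σ 6°
around a 14° preferred amplitude) for two reasons: the half-max regions
then span several cells/bins, so the mean over them varies smoothly
instead of jumping when one borderline bin crosses the threshold, and the
preferred amplitude sits in the long band, which uniform screen-wide
free-viewing saccades populate densely (the medium band, 5–10°, collects
only a handful of saccades per direction bin in a session of this length
— a real limitation of uniform gaze targets that the recovery tests must
respect).

**What the simulator does not capture.** Tracker noise is white, not the
colored noise plus blink/pupil artifacts of video eye tracking; there is
no drift, no smooth pursuit, no microsaccades, no glissades; saccade
curvature is zero; spike trains have no refractoriness, bursting
dynamics, or latency jitter; gaze targets during free viewing are uniform
rather than salience-driven, which under-represents short saccades
relative to real scanpaths. Passing recovery tests therefore shows the
analysis chain is correct under its stated model, not that it is robust
to every artifact of real recordings.

## Numerical and scale choices

Problem sizes in the test suite were picked so the full suite runs in
well under a minute of CPU for the unit tests plus a few minutes for the
end-to-end recovery checks: calibration recovery uses twenty 10-minute
sessions at 120 Hz; detector accuracy uses 200 saccades at 1 kHz; RF
recovery uses 6 repetitions per cell over 40 seeds; MF recovery uses
900 s of free viewing per seed (dictated by the medium-band count noted
above); the depth-trend check uses one layered bundle. Determinism is
asserted by serializing whole bundles. All window logic is half-open and
all bin assignments are exhaustive and exclusive, so counts are conserved
— both properties are tested against independent brute-force tallies,
bit for bit.
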
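---
title: "Methods behind motionkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind motionkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionkit)
```

motionkit analyses tracked point-of-interest (POI) coordinates together
with electrophysiology and sensor traces. This vignette documents the
quantitative conventions the package commits to, why they were chosen, and
what the synthetic validation does and does not demonstrate.

## Data model and units

The package is strictly unit-agnostic. A `poi_trajectory` stores times and
an `n × d` coordinate matrix (`d` of 2 or 3) exactly as imported; derived
quantities inherit the input units (mm and s in, mm/s out). `rescale_time()`
is the only unit hook — it multiplies timestamps by a constant so that, for
example, millisecond exports can be combined with second-based recordings.

Missing samples (tracking dropouts, pose-estimation frames below a
likelihood threshold) are represented by an explicit per-sample mask rather
than magic numbers, with the coordinate rows set to `NA` sentinels. The mask
survives every file round trip, and every statistic excludes masked
samples; derivative intervals touching a masked sample are themselves
reported missing.

Coordinates follow the Cartesian convention with y increasing upward. Data
from image-coordinate trackers (y down) must be converted with
`invert_axis()`; the gait logic (e.g. "maximum toe-lift") assumes
up-positive vertical and would silently invert its meaning otherwise. 2D
data never acquire an implicit third coordinate in analysis; a constant
placeholder z is attached only at render time, for perspective drawing.

Every preprocessing and signal operation is pure: it returns a new object
and appends exactly one entry to the processing history. Signal traces
additionally keep an immutable copy of their raw samples, so
`revert_trace()` always restores the original recording.

## Kinematics

Speeds are forward differences, `v_i = (p_{i+1} − p_i)/(t_{i+1} − t_i)`,
not central differences or spline derivatives. This is the "instant speed"
of frame-to-frame video tracking, and it makes the validation cases exact:
a linear coordinate gives a constant speed and identically zero
acceleration, and a quadratic coordinate sampled at Δt = 1 gives speeds
2t + 1 and a constant acceleration of 2. Accelerations divide successive
speed differences by the half-sum of the two spanned intervals,
`a_i = 2(v_{i+1} − v_i)/(t_{i+2} − t_i)`, and are timestamped at the
midpoint of the spanned interval so they align symmetrically when plotted
against other series. A consequence worth knowing: a single bad coordinate
sample corrupts exactly two speed samples and three acceleration samples,
no more — the test suite asserts this locality.

Joint angles are the interior, unsigned angle at the vertex,
`θ = atan2(‖u×v‖, u·v)` with `u = A − B`, `v = C − B`, in `[0°, 180°]`.
The `atan2` form is numerically stable where the arccosine of a normalised
dot product loses digits (near 0° and 180°). No signed/winding convention
is offered; frames where a segment has zero length yield a missing value
rather than an error, since real markers do occasionally coincide.

Stick-diagram normalization subtracts the reference POI's displacement
since the first frame, on the selected axes only. This anchors the
reference point while preserving the initial pose. It is a display
transform: gait and kinematic computations always run on raw coordinates,
and the tests verify that normalization leaves them unchanged.

`describe()` reports the sample standard deviation (n − 1), defines the
mode as the most frequent value after rounding to a configurable number of
decimals (continuous data have no repeated values otherwise), and breaks
mode ties toward the smallest value so results are deterministic.

## Preprocessing choices

The outlier detector is median ± k·1.4826·MAD per POI and axis, with k
defaulting to 3 — the standard robust sigma rule. The replacement methods
(linear interpolation, nearest, previous, mean window of width 5 by
default) also fill masked samples, making this the gap-repair step. An axis
whose MAD is zero is skipped with a warning: its threshold would degenerate
and flag every deviation from the median.

Smoothing windows are centered and must be odd; edges use shrinking windows
instead of padding, so no data is fabricated at trajectory ends — the first
sample is averaged over whatever neighbours exist. Trimming is a closed
interval on *time*, not on indices, so the same window means the same thing
across recordings with different sampling rates.

Stitching two camera views keeps the base recording strictly before the
transition time and the patch from the transition on, with no blending; the
patch may be rotated about its centroid and translated to reconcile the two
frames of reference. Perspective-size correction is plain isotropic scaling
about a center — no projective camera model is attempted, and lens
distortion must be corrected before import. A residual gap at the
transition larger than twice the median sampling interval triggers a
warning rather than an error, since operators sometimes stitch across a
deliberate cut.

`downsample_view()` exists for display only. Its output carries a tag that
`kinematics()` refuses, because thinning samples changes derivative
estimates; the tag enforcement turns a subtle numerical error into a loud
contract error.

## Signal processing

Butterworth filters (any order, low/high/band/stop) are applied forward and
backward by default (`filtfilt`), doubling the effective order but
cancelling group delay. Zero-phase filtering matters here because filtered
signals feed the phase-lag estimator; a causal single pass (available via
`zero_phase = FALSE`) would inject a frequency-dependent lag into exactly
the quantity being measured.

The periodogram is normalised as `|X_k|²/n²` with one-sided doubling of all
bins except DC and Nyquist, so the powers sum to the mean square of the
signal. This Parseval identity is asserted (to 1e-6 relative) on every
spectrum in the test suite — the normalisation is chosen to be testable. A
unit-amplitude tone therefore carries one-sided power 0.5 at its bin.
Spectrograms default to a 256-sample Hann window with 50% overlap, common
practice for biosignals.

Rectification: "mean" removes the DC offset (`x − mean(x)`, the baseline
step before full-wave rectification), "absolute" and "square_root"
(per-sample `√(x²)`) are numerically identical and both kept as named
methods, and "half_wave" clamps negatives to zero. The linear-envelope
method checks the processing history and refuses to low-pass a signal that
was never rectified (overridable with `force = TRUE`), because the low-pass
of a zero-mean oscillation is near zero, a classic silent mistake. The
Hilbert envelope is the magnitude of the analytic signal, built by the
standard FFT construction (positive frequencies doubled, negative zeroed).

## Correlation machinery

`harmonize()` trims two series to their overlapping time range and linearly
resamples both to the *lower* of the two rates. Downsampling was chosen
over upsampling because interpolation to a higher rate fabricates detail
that correlation statistics would then treat as data.

Auto- and cross-correlation use the normalised cross-covariance with full-
series means and denominators, so the autocorrelation is exactly 1 at lag
zero and all coefficients lie in [−1, 1]. The phase-lag/amplitude-ratio
estimator takes the peak frequency of the **first** signal's FFT magnitude
(DC excluded) and reads both FFTs at that single bin: a common frequency is
what makes a phase *difference* well defined when the two spectra peak at
different bins. The ratio is second over first, and the lag is wrapped to
(−180°, 180°]. Accuracy is best over an integer number of periods; the sine
generators round their duration up to guarantee this, and exclude the
endpoint sample so each component sits exactly on a bin.

Dynamic time warping uses per-sample cost `|a_i − b_j|`, the symmetric step
set {down, right, diagonal} without slope weighting, and a Sakoe–Chiba band
`|i − j| ≤ band`. The simplest standard form was chosen deliberately so the
implementation can be checked against an exhaustive dynamic-programming
oracle in the tests; a band smaller than the length difference is rejected
up front as infeasible. Kendall correlation is the tie-corrected tau-b as
computed by `stats::cor`.

## Gait analysis

Events are first-class inputs (type, side, frame index), mirroring
interactive marking; analyses never depend on how events were produced.
Cycles are delimited by successive ipsilateral heel-strikes, and the stream
must *start* with a heel-strike — enforcing this ordering is what makes
stance + swing = stride hold by construction. Stride length is measured on
the heel POI along a user-chosen progression axis (default x): projecting
on the travel axis is robust to vertical bobbing, and which marker the
length is read from is explicit and configurable. Stance intervals are
closed-open `[heel-strike, toe-off)`; double-support overlap is pairwise
interval intersection with zero-length intersections discarded. The
two-phase variant (swim power/return strokes) reuses the same machinery
with alternating entry/mid events and side `"none"`.

The heuristic detector is a convenience for clean recordings: a ground
candidate is a frame whose marker height is within `height_frac` (default
0.05) of the height range above the minimum *and* whose progression speed
is below `speed_frac` (default 0.1) of the maximum. Because a smoothly
decelerating foot can satisfy these loose conditions a few frames before
actual contact, each contact run is refined to its ground plateau: the
strike is the first frame at the run's minimum height, lift-off the last.
On the synthetic gait this recovers every annotated event to within one
frame; on noisy real data it remains an assistant, not a substitute for
inspection.

## Synthetic fixtures and what the tests show

The generators reproduce the validation inputs exactly and deterministically
(identical parameters give bit-identical output; optional noise requires an
explicit seed and never touches the stored ground truth):

* polynomial trajectory — x linear (coefficients 0, 2), y quadratic
  (0, 0, 1), Δt = 1 over [0, 10], with an optional injected outlier;
* angle chain — one static frame per angle, A = (0,0), B = (1,0),
  C = B + (cos(180° − θ), sin(180° − θ)), so the interior angle at B is θ
  by construction (static frames isolate the angle operator from motion);
* dummy gait — heel-strikes at positions 0, 7, 14 at times 0, 6, 12 s,
  stance 4 s, toe apex 0.5, sampled at 100 Hz so every event lies exactly
  on a sample; the geometry is engineered to make stride length 7, stance
  4 s, swing 2 s and toe-lift 0.5 hold exactly, and a contralateral copy
  offset by half a stride supports step parameters (duration 3 s, size 3.5);
* sine mixture — unit tones at 25, 30, 35 Hz, 1 kHz, 10 s; antiphase pair —
  5 Hz, ratio 2, phase π, same sampling.

These fixtures validate the *computational* pipeline: exact arithmetic on
noiseless, perfectly sampled, perfectly annotated data. They do not emulate
soft-tissue artefact, marker occlusion, pose-estimation jitter, EMG
crosstalk or non-stationary sampling, so passing tests demonstrate
correctness of the implemented definitions, not robustness on real
recordings — the preprocessing tools exist precisely because real data
violate these idealisations.

Problem sizes were chosen at desk scale: 10 s of 1 kHz signal for spectral
checks (0.1 Hz bins, so the 25/30/35 Hz tones are widely separated),
12 s of 100 Hz gait (1201 samples), length-10 series for the exhaustive
DTW oracle.

## File formats and the session archive

Delimited text (comma/semicolon/tab, auto-detected; decimal comma only via
an explicit `decimal = ","` flag, never guessed, since it is ambiguous with
semicolon delimiters), spreadsheet workbooks (read via readxl), and the
three-header DeepLabCut CSV dialect (frame-to-time conversion requires an
explicit `fps`; likelihood filtering defaults to off). Text exports use 17
significant digits, which round-trips IEEE doubles exactly.

The session archive is a ZIP container holding a JSON manifest (names,
types, processing histories, gait annotation) plus one CSV payload per
dataset — open, diffable and lossless: `load_session(save_session(s))`
reproduces `s` exactly, including missing masks and raw signal copies.
Spreadsheet *writing* is not provided (csv/txt only).

## Known limitations

No camera calibration, lens-distortion correction or 3D triangulation; no
torque or inverse dynamics; no coherence or Granger-style analysis; no
automatic left/right limb assignment. The DTW implementation is plain R
and intended for the band-constrained regime (thousands of samples with a
modest band, or short series unconstrained). GIF/AVI containers are not
written; animations export as PNG or SVG frame sequences with a playback
manifest.
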
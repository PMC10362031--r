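---
title: "Contactless seismocardiography from chest video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless seismocardiography from chest video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Seismocardiography records the small vibrations the beating heart imprints
on the chest wall. The conventional instrument is an accelerometer taped to
the sternum; `scgvision` implements the camera-only alternative: a
high-contrast artificial target (in practice a texture-patterned sticker)
is filmed at 60 fps, its sub-pixel motion is tracked, converted to
millimeters, and twice differentiated into acceleration. The scientific
question the package's validation half answers is whether that
vision-based signal agrees with what a chest-mounted accelerometer would
have measured, and whether heart rate can be read off it.

Two properties of the problem shape everything downstream. First, the
motion of interest is tiny — tenths of a pixel at plausible
camera-to-chest geometries — so the tracker must be accurate to a few
hundredths of a pixel. Second, a 60 fps camera is blind above 30 Hz, so
all cross-instrument comparisons are restricted to the 1–30 Hz band and
reference channels are bandpassed accordingly.

## Tracking model

The tracker is the classic Lucas–Kanade template alignment scheme,
specialized to pure translation. The template is cut once, from frame 1;
the warp is `W(x; u) = x + u`; each frame minimizes the
sum-of-squared-differences error by Gauss–Newton iteration, with the warp
Jacobian equal to the 2×2 identity so the Hessian reduces to the sum of
gradient outer products. Design choices the underlying publications of
this family of methods leave open, and how this package resolves them:

* **Interpolation**: bilinear, matching the first-order Taylor model.
* **Gradients**: central differences on the full frame, bilinearly sampled
  at the warped positions (the forward-additive variant).
* **Convergence**: `epsilon = 0.01` px on the increment norm, capped at 50
  iterations. After the first sub-epsilon increment the solver runs two
  further "polish" iterations: convergence is locally quadratic, so these
  land within ~1e-10 px of the SSD optimum and exactly representable
  motions (integer shifts) are recovered exactly. The lowest-error iterate
  is returned, which also guarantees the per-frame error never exceeds the
  error at the initial guess.
* **Initialization**: each frame starts from the previous frame's converged
  motion; inter-frame motion is far smaller than the template, so this is
  safe and fast.
* **Degeneracy**: a Hessian eigenvalue ratio above 1e6 raises an
  untrackable-texture error; a constant-intensity template is rejected at
  extraction time.
* **Template updating**: off by default. An optional drift-corrected mode
  re-cuts the template every `m` frames and re-aligns against the frame-1
  template to cancel accumulated drift; for millimeter-scale cardiac motion
  the appearance change is negligible and the static template performs
  identically, which is why the default is off.
* **Coordinates**: 0-based, origin top-left, `x` = column, `y` = row; ROIs
  are half-open rectangles. Rotation to align the target with the camera
  axes is a user-supplied per-ROI angle applied at load time.

Displacement is referenced to frame 1 (the template's frame), not
accumulated between consecutive frames, so tracking errors do not
integrate over the recording.

## Calibration and differentiation

With the target plane parallel to the image plane, one scaling factor
converts pixels to millimeters: `SF = D_mm / D_pixel` from the target's
known physical size, or `d·p/f` from pinhole intrinsics. Acceleration is
the central second difference times `fs^2`, endpoints replicated; on a
5000 Hz grid this is indistinguishable from the analytic second derivative
for sub-30 Hz content, and on the 60 Hz camera grid it attenuates a
component at frequency `f` by `sinc^2(pi f / 60)` relative to the analytic
value — about 17% at 14 Hz. This droop affects amplitudes within the
oscillatory bursts but barely affects waveform correlation, because the
bursts are time-disjoint.

## Resampling design

The vision signal (60 Hz) and the reference channels (5000 Hz) must meet
on a common grid. Plain linear interpolation upward creates spectral
images of the baseband above the source Nyquist frequency and bakes a
`sinc^2` droop into the baseband. The package therefore upsamples by
linear interpolation followed by a zero-phase-compensated FIR filter on
the new grid that does two jobs at once: it rejects the interpolation
images above the source Nyquist and equalizes the droop across the
passband (up to 88.5% of the source Nyquist; `fir2` design, adaptive
length up to 2501 taps, unit DC gain, edge-slope-extrapolated padding so
constants and ramps pass exactly). Decimation is plain interpolation onto
the coarser grid, with the documented assumption — true everywhere in this
pipeline, by construction or prior bandpass — that the signal is
band-limited below the target Nyquist. With this design a
60 → 5000 → 60 Hz round trip of sub-25 Hz content is preserved to well
under 1% RMS, which is the property the rest of the validation chain
depends on.

All bandpass filtering is a fourth-order Butterworth (two poles per edge)
run forward-backward, because beat *timing* is compared across
instruments and net phase must be zero. Whether the original
instrumentation filtered with zero phase is not knowable from outside;
zero phase is the defensible choice and is applied to both channels
equally.

## Synchronization and beats

Independently clocked recorders are aligned by microphone taps at the
start and end of each recording: a short-time energy envelope (20 ms
window) thresholded at 8× its median marks tap onsets, and the two-anchor
affine map `t_dst = offset + drift·t_src` (drift sanity-checked to
[0.9, 1.1]) synchronizes the clocks exactly at the anchors.

R peaks come from a Pan–Tompkins chain — 5–15 Hz bandpass, derivative,
squaring, 150 ms moving-window integration, adaptive dual thresholds with
200 ms refractory and search-back — with candidates taken as the tallest
integrated-envelope peak in any refractory-length neighbourhood (the
envelope of one QRS is a plateau with several local maxima; taking the
first crossing instead biases detections early). Detections are refined to
the local maximum of the filtered ECG within ±25 ms. All thresholds adapt
multiplicatively, so detection is exactly invariant to amplitude scaling.

Beats are segmented on the common grid as
`[n_i - floor(n_c/4), n_i - floor(n_c/4) + n_c)`, one quarter cycle before
each R wave and three quarters after, with `n_c` the rounded mean RR
interval of the recording. Flooring the quarter keeps every window exactly
`n_c` samples, which the similarity index requires; windows that cross the
record boundary are dropped and reported, not padded. The ensemble average
is the pointwise mean across beats.

## Agreement metrics

**DTW similarity.** The local cost is `|a_i - b_j|` (the natural scalar
Euclidean metric); steps are down/right/diagonal; the warping path is
restricted to a corridor of half-width `ceil(0.05 · max(n, m))` cells
around the straight-line fit between the endpoints. The corridor is
measured along *either* index axis (a cell is admissible if it is within
the band horizontally or vertically), which makes the constraint — and
hence the distance — symmetric under argument swap even for unequal
lengths. The similarity index is `S = (M - D)/M` with `M` the maximum
absolute value of the *gold-standard ensemble average* times `n_c`; the
alternative reading of `M` (maximum over raw segments) is not used because
`S` compares the ensemble arguments themselves. `S` values outside [0, 1]
are flagged, never clamped: the boundedness of `S` is an empirical
property of well-behaved signal pairs, not a mathematical guarantee.

**Wavelet coherence.** Continuous transforms with the analytic Morlet
wavelet (center frequency 6), 12 voices per octave, scales spanning 30 Hz
down to `max(0.5, 2/duration)` Hz. The coherence smoothing operator is a
per-scale time boxcar spanning one wavelet e-folding time (`sqrt(2)·s`) on
each side, then a boxcar over 7 adjacent scales (about half an octave).
These widths were chosen once, from the estimator's statistics: with
materially narrower smoothing the coherence of *independent* noise is
biased above 0.5 — an estimator that cannot distinguish coupled from
uncoupled signals — while at the chosen widths independent white noise
averages ≈0.38 in-cone and self-coherence remains exactly 1 by
construction. The cone of influence marks, per column, the boundary
frequency below which the e-folding radius of the wavelet crosses the
record edge; summaries only average cells inside the cone. Within the
pipeline, coherence is computed on signals decimated to 200 Hz — the
content band ends at 30 Hz, so this changes nothing but the cost.

**Heart rate.** From ECG, `bpm_i = 60/RR_i` per consecutive R pair. From
the vision SCG, the deliberately simple estimator: 0.7–1.5 Hz zero-phase
bandpass, then peak picking with 0.4 s minimum separation (a 150 bpm
ceiling) and prominence at least a quarter of the filtered signal's
standard deviation. Peaks within one low-cutoff period (≈1.4 s) of either
record edge are discarded: the zero-phase filter's startup transient
shifts them by tens of milliseconds, which is enough to corrupt a mean
over a short record. This class of estimator is known to underestimate
slightly at high rates and scatter below 60 bpm; no correction is applied,
the limitation is inherited deliberately. Agreement with ECG is summarized
as Bland–Altman bias and `bias ± 1.96·SD` limits.

## The synthetic data, and what it does not show

Recordings of the kind this pipeline targets are not shareable, so the
package generates its own ground truth. The displacement waveform carries,
per beat: two Gabor-like oscillatory bursts (carriers 14 and 10 Hz,
amplitudes 0.10 and 0.07 mm, centered at 5% and 35% of the cycle) standing
in for the two intra-beat vibration packets; a 0.03 mm bulk oscillation at
the beat fundamental, representing slow cardiac recoil of the chest —
without *some* energy at the fundamental, a 0.7–1.5 Hz heart-rate
estimator has nothing physical to detect; and seeded 1/f noise at
0.002 mm RMS, band-limited to 0.2–25 Hz. Spectral energy above 30 Hz is
below 1% of the total, matching what a 60 fps camera can observe. The
rendered scene composites an 80–96 px smoothed-noise texture patch onto a
static background at sub-pixel positions via closed-form bilinear
resampling at 0.1 mm/px, with exact displacement, acceleration (dense-grid
second difference at 5000 Hz), ECG, and calibration attached. All
generators are pure functions of their parameters and seed.

What passing these tests shows: the tracker, calibration,
differentiation, resampling, segmentation and metric code recover known
physical parameters through the full chain at realistic amplitudes and
rates. What it does not show: robustness to skin and fabric appearance,
lighting changes, camera shake, rolling shutter, respiration or gross body
motion, electrode artifacts, or arrhythmic rhythms — none of which the
renderer emulates. Axis misalignment between a tilted accelerometer and
the camera, a real effect on real chests, is likewise absent.

One renderer–tracker interaction deserves note: the renderer defines frame
content as bilinear samples of the texture, and the tracker re-interpolates
those samples bilinearly at warped positions. The composition of two
bilinear kernels is not a bilinear kernel, so at fractional true offsets
the SSD optimum sits ~0.03 px from the truth for the default texture
sharpness. The fully converged tracker therefore shows an RMSE of about
0.03 px on sub-pixel sinusoids — within the 0.05 px design target, and an
honest reflection of interpolation-model mismatch rather than of solver
error (integer offsets, where the mismatch vanishes, are recovered to
1e-10 px).

## Problem sizes and determinism

The shipped tests and the acceptance script run 10-second scenes at 60 fps
(128×128 px frames, ~80 px templates), reference channels at 5000 Hz, and
coherence at 200 Hz — sizes chosen so the whole suite exercises every
stage, including two full end-to-end scenes, in about two minutes on one
core. File-based pipeline tests use 6-second scenes at a 500 Hz analysis
rate. Every random element — textures, noise, ECG jitter — flows from
explicit integer seeds, and re-running any pipeline with the same
configuration produces byte-identical outputs.

## Known limitations

* Only in-plane (right-to-left and head-to-foot) motion; the dorsoventral
  SCG component is invisible to a single fronto-parallel camera.
* Content above half the frame rate is unobservable; the 1–30 Hz band is a
  hard ceiling at 60 fps.
* The translation-only warp assumes a flat target parallel to the image
  plane; rotation or perspective change is not modeled.
* The heart-rate estimator is intentionally basic (band + peaks); its
  high-rate underestimation is documented above.
* Decimation assumes band-limited input rather than enforcing it with an
  antialiasing stage; callers decimating broadband signals must bandpass
  first.
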
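# scgvision

Contactless seismocardiography (SCG) from chest video, in R.

SCG measures the millimeter-scale vibrations of the chest wall produced by
the heart's mechanical activity — valve openings and closures, ejection,
rapid filling. It is conventionally recorded with accelerometers taped to
the sternum. `scgvision` implements a camera-only alternative: a
high-contrast target on the chest is tracked through a 60 fps video at
sub-pixel resolution, the tracked displacement is converted to millimeters
by camera calibration and twice differentiated into acceleration, and the
resulting vision-based SCG is validated against reference accelerometer and
ECG channels with the field's standard agreement metrics.

## What is inside

**Tracking.** A Lucas–Kanade template tracker for pure translation. With
template `T(x)` cut from frame 1 and warp `W(x; u) = x + u`, each frame
minimizes the sum-of-squared-differences error

    E(u) = sum_x [ I_n(W(x; u)) - T(x) ]^2

by Gauss–Newton iteration `u <- u + H^-1 sum_x (grad I_n)^T [T - I_n(W)]`,
with `H = sum_x (grad I_n)^T (grad I_n)` and bilinear sub-pixel
interpolation. Pixel motion becomes millimeters through the scaling factor
`SF = D_mm / D_pixel` (or `d·p/f` from pinhole intrinsics).

**Signal processing.** Second-difference acceleration, droop-equalized
resampling between the camera rate (60 Hz) and the reference rate
(5000 Hz), zero-phase Butterworth bandpass (1–30 Hz), microphone-tap clock
synchronization, Pan–Tompkins R-peak detection, beat segmentation around
each R wave (`[n_i - n_c/4, n_i + 3 n_c/4)` with `n_c` the mean cycle
length), and ensemble averaging.

**Validation metrics.** Pearson correlation of beat ensembles; a
band-constrained dynamic-time-warping similarity index
`S = (M - D) / M`, where `D` is the DTW distance within a 5% corridor and
`M` is the maximum absolute gold-standard amplitude times the segment
length; cross-correlation lag; magnitude-squared wavelet coherence with the
analytic Morlet wavelet (0.5–30 Hz, cone of influence); and Bland–Altman
heart-rate agreement.

**Synthetic scenes.** Because physiological recordings of this kind are
IRB-restricted, the package generates its own ground truth: cardiac-like
displacement waveforms (two oscillatory bursts per beat plus a small bulk
motion at the beat fundamental), rendered videos of a textured patch moving
by those waveforms via closed-form bilinear resampling, and synthetic ECG
with known R-peak times. Every stage is tested against these exact
references.

## Worked example

```r
library(scgvision)

scene <- make_synthetic_scene(hr_bpm = 72, duration = 10, seed = 11)
report <- analyze_scene(scene)
print(report)
```

```
<scene_report>
  x: r = 0.998, S = 0.993, lag = -0.2 ms, coh = 0.945
  y: r = 0.999, S = 0.991, lag = -0.2 ms, coh = 0.947
  HR: ecg 72.0 bpm, scg 72.0 bpm (programmed 72.0)
```

Reading: the vision-based SCG reconstructed from the rendered 60 fps video
correlates at `r = 0.998` with the true (bandpassed) acceleration, the
DTW similarity index is `S = 0.993`, the residual lag between the channels
is a fraction of a millisecond, mean in-cone wavelet coherence is 0.95, and
the heart rate recovered from the vision signal alone matches the
programmed 72 bpm.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/scgvision.R synth --hr 72 --duration 10 --seed 7 --out scene/
Rscript inst/cli/scgvision.R track --video scene/frames --fps 60 \
    --roi 24,24,80,80 --target-mm 8 --target-px 80 --out traj.csv
```

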
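#' Cardiac-like chest displacement waveform
#'
#' A ground-truthed stand-in for millimeter-scale cardiac chest motion:
#' each beat carries two Gabor-like oscillatory bursts (the systolic and
#' diastolic vibration packets, centered at 5% and 35% of the cycle with
#' carriers of 14 and 10 Hz and amplitudes of 0.1 and 0.07 mm), a small
#' bulk chest oscillation at the beat fundamental (0.03 mm), and seeded
#' low-level 1/f noise band-limited below 25 Hz. The waveform is periodic
#' at `hr_bpm / 60` Hz and its spectral energy above 30 Hz is below 1% of
#' the total, matching what a 60 fps camera can observe. It is a
#' non-physiological but band- and amplitude-faithful surrogate.
#'
#' @param hr_bpm heart rate, 30-180 bpm.
#' @param duration record length, seconds.
#' @param fs sampling frequency, Hz (>= 120).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param noise_rms_mm RMS of the 1/f noise floor, millimeters.
#' @return A [uniform_signal()] in `"mm"`.
#' @export
make_scg_waveform <- function(hr_bpm, duration, fs, seed = 1L,
                              noise_rms_mm = 0.002) {
  if (hr_bpm < 30 || hr_bpm > 180) {
    stop_scg("scg_domain_error", "hr_bpm must be in [30, 180], got %g", hr_bpm)
  }
  if (fs < 120) stop_scg("scg_domain_error", "fs must be >= 120 Hz")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  tb <- 60 / hr_bpm
  x <- 0.03 * sin(2 * pi * t / tb)  # bulk cardiac chest motion, fundamental
  bursts <- list(
    list(frac = 0.05, carrier = 14, sigma = 0.030, amp = 0.10),
    list(frac = 0.35, carrier = 10, sigma = 0.035, amp = 0.07)
  )
  n_beats <- ceiling(duration / tb) + 1L
  for (k in 0:(n_beats - 1L)) {
    for (bu in bursts) {
      ctr <- k * tb + bu$frac * tb
      x <- x + bu$amp * exp(-(t - ctr)^2 / (2 * bu$sigma^2)) *
        cos(2 * pi * bu$carrier * (t - ctr))
    }
  }
  if (noise_rms_mm > 0) {
    x <- x + with_seed(seed, pink_noise(n, fs, f_lo = 0.2, f_hi = 25)) *
      noise_rms_mm
  }
  uniform_signal(x, fs = fs, units = "mm")
}

# Band-limited 1/f noise with unit RMS, shaped in the Fourier domain.
pink_noise <- function(n, fs, f_lo, f_hi) {
  nz <- 2^ceiling(log2(n))
  freqs <- seq(0, fs / 2, length.out = nz / 2 + 1)
  amp <- numeric(nz / 2 + 1)
  band <- freqs >= f_lo & freqs <= f_hi
  amp[band] <- 1 / sqrt(freqs[band])
  phase <- runif(nz / 2 + 1, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  half[1] <- 0
  spec <- c(half, Conj(rev(half[2:(nz / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

#' Synthetic ECG with known R-peak times
#'
#' A Gaussian-bump morphology model: a tall narrow R wave per beat with
#' small Q/S deflections and P/T humps, optional RR jitter, optional 0.3 Hz
#' baseline wander, and seeded Gaussian noise at a prescribed SNR. The true
#' R-peak sample indices are returned alongside the trace.
#'
#' @param hr_bpm heart rate, bpm.
#' @param duration seconds.
#' @param fs sampling frequency, Hz (>= 100).
#' @param snr_db signal-to-noise ratio of the additive noise; `Inf` for a
#'   clean trace.
#' @param seed integer seed.
#' @param rr_jitter_frac RR-interval jitter as a fraction of the mean RR
#'   (<= 0.02).
#' @param baseline_amp amplitude of 0.3 Hz baseline wander, mV.
#' @return List with `ecg` (a [uniform_signal()], mV) and `rpeaks` (an
#'   [r_peak_series()] of the true beat positions).
#' @export
make_synthetic_ecg <- function(hr_bpm, duration, fs, snr_db = Inf, seed = 1L,
                               rr_jitter_frac = 0, baseline_amp = 0) {
  if (fs < 100) stop_scg("scg_domain_error", "ECG fs must be >= 100 Hz")
  if (rr_jitter_frac < 0 || rr_jitter_frac > 0.02) {
    stop_scg("scg_domain_error", "rr_jitter_frac must be in [0, 0.02]")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  tb <- 60 / hr_bpm
  with_seed(seed, {
    n_beats <- ceiling(duration / tb) + 2L
    rr <- rep(tb, n_beats)
    if (rr_jitter_frac > 0) {
      rr <- rr * (1 + runif(n_beats, -rr_jitter_frac, rr_jitter_frac))
    }
    beat_t <- cumsum(c(0.4, rr[-1L]))  # first R at 0.4 s
    beat_t <- beat_t[beat_t < duration - 1 / fs]
    gauss <- function(ctr, sigma, amp) {
      out <- numeric(n)
      for (ct in ctr) out <- out + amp * exp(-(t - ct)^2 / (2 * sigma^2))
      out
    }
    x <- gauss(beat_t, 0.008, 1.0) +          # R
      gauss(beat_t - 0.025, 0.006, -0.12) +   # Q
      gauss(beat_t + 0.030, 0.007, -0.20) +   # S
      gauss(beat_t - 0.180, 0.025, 0.12) +    # P
      gauss(beat_t + 0.250, 0.055, 0.30)      # T
    if (baseline_amp > 0) {
      x <- x + baseline_amp * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))
    }
    if (is.finite(snr_db)) {
      noise_sd <- sqrt(mean(x^2) / 10^(snr_db / 10))
      x <- x + rnorm(n, 0, noise_sd)
    }
    list(
      ecg = uniform_signal(x, fs = fs, units = "mV"),
      rpeaks = r_peak_series(round(beat_t * fs) + 1L, fs)
    )
  })
}

#' Render a video of a textured target moving by a known waveform
#'
#' Composites a band-limited high-contrast texture patch (smoothed seeded
#' noise) onto a static low-contrast background, translating it each frame
#' by the prescribed displacement via closed-form bilinear resampling - so
#' the scene's ground truth displacement is exact by construction. Frames
#' are sampled from the waveforms at the frame times.
#'
#' @param waveform_x,waveform_y [uniform_signal()]s of displacement in mm
#'   (band-limited below `fps / 2`).
#' @param scale_mm_per_px ground-truth calibration, mm per pixel.
#' @param fps frame rate of the rendered video.
#' @param texture_seed integer seed for the texture and any sensor noise.
#' @param frame_size `c(width, height)` of the rendered frames, pixels.
#' @param patch_px side of the textured patch, pixels.
#' @param noise_sd additive sensor noise per pixel (intensity units);
#'   0 disables it.
#' @return A `synthetic_scene` with `frames` (a [frame_sequence()]),
#'   `truth_displacement` (list `x`, `y` of [uniform_signal()]s in px,
#'   relative to frame 1), `truth_displacement_mm` (same in mm),
#'   `scale_mm_per_px`, and `suggested_roi` (a margin-safe tracking ROI
#'   strictly inside the patch).
#' @export
render_video <- function(waveform_x, waveform_y, scale_mm_per_px, fps,
                         texture_seed = 1L, frame_size = c(128L, 128L),
                         patch_px = 96L, noise_sd = 0) {
  stopifnot(inherits(waveform_x, "uniform_signal"),
            inherits(waveform_y, "uniform_signal"))
  w <- frame_size[1L]; h <- frame_size[2L]
  dur <- min(signal_duration(waveform_x), signal_duration(waveform_y))
  nf <- floor(dur * fps) + 1L
  ft <- (seq_len(nf) - 1L) / fps
  dx_mm <- approx(signal_times(waveform_x), waveform_x$values, xout = ft)$y
  dy_mm <- approx(signal_times(waveform_y), waveform_y$values, xout = ft)$y
  dx <- dx_mm / scale_mm_per_px
  dy <- dy_mm / scale_mm_per_px
  ox <- round((w - patch_px) / 2); oy <- round((h - patch_px) / 2)
  guard <- min(ox, oy, w - ox - patch_px, h - oy - patch_px) - 2
  if (max(abs(c(dx - dx[1L], dy - dy[1L]))) > guard) {
    stop_scg("scg_render_bounds_error",
             "motion exceeds the %g px guard margin of the rendered patch",
             guard)
  }
  with_seed(texture_seed, {
    texture <- smoothed_texture(patch_px, patch_px, sigma = 1.2)
    background <- 0.35 + 0.1 * smoothed_texture(h, w, sigma = 4)
    frames <- vector("list", nf)
    # patch support region in the frame, with room for the motion
    rx <- max(1L, ox - floor(guard)):min(w, ox + patch_px + ceiling(guard))
    ry <- max(1L, oy - floor(guard)):min(h, oy + patch_px + ceiling(guard))
    gx <- rep(rx - 1L, each = length(ry))   # 0-based frame coords
    gy <- rep(ry - 1L, times = length(rx))
    for (k in seq_len(nf)) {
      fr <- background
      tx <- gx - ox - dx[k]   # texture-local coordinates
      ty <- gy - oy - dy[k]
      inside <- tx >= 0 & tx <= patch_px - 1 & ty >= 0 & ty <= patch_px - 1
      vals <- fr[cbind(gy + 1L, gx + 1L)]
      vals[inside] <- bilinear_sample(texture, tx[inside], ty[inside])
      fr[cbind(gy + 1L, gx + 1L)] <- vals
      if (noise_sd > 0) fr <- fr + matrix(rnorm(h * w, 0, noise_sd), h, w)
      frames[[k]] <- pmin(pmax(fr, 0), 1)
    }
    structure(
      list(
        frames = frame_sequence(frames, fps),
        truth_displacement = list(
          x = uniform_signal(dx - dx[1L], fps, units = "pixel"),
          y = uniform_signal(dy - dy[1L], fps, units = "pixel")
        ),
        truth_displacement_mm = list(
          x = uniform_signal(dx_mm - dx_mm[1L], fps, units = "mm"),
          y = uniform_signal(dy_mm - dy_mm[1L], fps, units = "mm")
        ),
        scale_mm_per_px = scale_mm_per_px,
        suggested_roi = c(ox + 8L, oy + 8L, patch_px - 16L, patch_px - 16L),
        seed = texture_seed
      ),
      class = "synthetic_scene"
    )
  })
}

# High-contrast band-limited texture: white noise blurred by a small
# Gaussian kernel, rescaled to [0.05, 0.95].
smoothed_texture <- function(h, w, sigma) {
  half <- max(2L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- half
  raw <- matrix(rnorm((h + 2 * pad) * (w + 2 * pad)), h + 2 * pad, w + 2 * pad)
  sm <- apply(raw, 2L, function(col) as.numeric(stats::filter(col, k, sides = 2L)))
  sm <- t(apply(sm, 1L, function(row) as.numeric(stats::filter(row, k, sides = 2L))))
  sm <- sm[(pad + 1):(pad + h), (pad + 1):(pad + w)]
  rng <- range(sm)
  0.05 + 0.9 * (sm - rng[1L]) / (rng[2L] - rng[1L])
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d frames @ %g fps, scale %g mm/px\n",
              length(x$frames$frames), x$frames$frame_rate, x$scale_mm_per_px))
  invisible(x)
}

#' Full ground-truthed recording: video, reference acceleration and ECG
#'
#' Generates a cardiac displacement waveform on a dense reference grid,
#' renders the 60 fps video of a textured patch moving by it (x axis; the
#' y axis gets the same waveform at reduced amplitude), and attaches the
#' reference channels a validation run needs: the true acceleration at
#' `truth_fs` (second difference of the dense displacement), a synthetic
#' ECG whose R peaks sit at the beat onsets, and the exact calibration.
#'
#' @param hr_bpm programmed heart rate, bpm.
#' @param duration seconds.
#' @param fps video frame rate.
#' @param seed integer seed driving every random element.
#' @param scale_mm_per_px calibration of the rendered scene.
#' @param truth_fs sampling rate of the reference channels, Hz.
#' @param noise_sd per-pixel sensor noise of the rendering.
#' @param y_scale amplitude ratio of the y-axis motion relative to x.
#' @return A `synthetic_scene` additionally carrying `truth_acceleration`
#'   (list `x`, `y`, m/s^2 at `truth_fs`), `truth_ecg`, `truth_rpeaks`,
#'   and `hr_bpm`.
#' @export
make_synthetic_scene <- function(hr_bpm = 72, duration = 10, fps = 60,
                                 seed = 1L, scale_mm_per_px = 0.1,
                                 truth_fs = 5000, noise_sd = 0,
                                 y_scale = 0.6) {
  wf_x <- make_scg_waveform(hr_bpm, duration, truth_fs, seed = seed)
  wf_y <- uniform_signal(y_scale * make_scg_waveform(
    hr_bpm, duration, truth_fs, seed = seed + 1L)$values,
    truth_fs, units = "mm")
  scene <- render_video(wf_x, wf_y, scale_mm_per_px, fps,
                        texture_seed = seed + 2L, noise_sd = noise_sd)
  ecg <- make_synthetic_ecg(hr_bpm, duration, truth_fs, snr_db = 20,
                            seed = seed + 3L)
  scene$truth_waveform_mm <- list(x = wf_x, y = wf_y)
  scene$truth_acceleration <- list(
    x = displacement_to_acceleration(wf_x),
    y = displacement_to_acceleration(wf_y)
  )
  scene$truth_ecg <- ecg$ecg
  scene$truth_rpeaks <- ecg$rpeaks
  scene$hr_bpm <- hr_bpm
  scene$seed <- seed
  scene
}
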
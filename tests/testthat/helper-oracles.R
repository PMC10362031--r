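# Independent oracles used by the metric tests. These deliberately do not
# share code with the package implementation.

# Exhaustive minimum-cost monotone alignment by top-down recursion over all
# admissible predecessors (memoized for tractability; every admissible path
# is explored through the recursion tree).
oracle_dtw <- function(a, b, band_fraction = NULL) {
  n <- length(a)
  m <- length(b)
  w <- if (is.null(band_fraction)) Inf else
    max(1, ceiling(band_fraction * max(n, m)))
  in_band <- function(i, j) {
    if (!is.finite(w)) return(TRUE)
    if (n == 1L || m == 1L) return(TRUE)
    jstar <- 1 + (i - 1) * (m - 1) / (n - 1)
    istar <- 1 + (j - 1) * (n - 1) / (m - 1)
    abs(j - jstar) <= w || abs(i - istar) <= w
  }
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i < 1L || j < 1L || !in_band(i, j)) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    c0 <- abs(a[i] - b[j])
    v <- if (i == 1L && j == 1L) c0 else {
      c0 + min(rec(i - 1L, j), rec(i, j - 1L), rec(i - 1L, j - 1L))
    }
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# Pure-tone uniform signal helper for analytic oracles.
tone <- function(freq, duration, fs, amp = 1, phase = 0, units = "a.u.") {
  t <- seq(0, duration, by = 1 / fs)
  uniform_signal(amp * sin(2 * pi * freq * t + phase), fs = fs, units = units)
}

# A small moving textured scene rendered from an arbitrary pixel-unit
# x-displacement; returns the scene plus the tracker-ready template.
scene_from_px_waveform <- function(dx_px, fps = 60, seed = 1L, scale = 0.1) {
  n <- length(dx_px)
  wf_x <- uniform_signal(dx_px * scale, fs = fps, units = "mm")
  wf_y <- uniform_signal(rep(0, n), fs = fps, units = "mm")
  render_video(wf_x, wf_y, scale_mm_per_px = scale, fps = fps,
               texture_seed = seed)
}
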
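# Continuous wavelet transform with the analytic Morlet wavelet
# (center frequency omega0 = 6), computed scale-by-scale in the Fourier
# domain on a zero-padded grid. Returns a [n_scales x n_samples] complex
# matrix. Scales are in seconds; frequency f = 1 / (fourier_factor * s).
morlet_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  nz <- 2^ceiling(log2(2 * n))
  xh <- fft(c(x, rep(0, nz - n)))
  dt <- 1 / fs
  k <- 0:(nz - 1)
  omega <- ifelse(k <= nz / 2, k, k - nz) * (2 * pi / (nz * dt))
  out <- matrix(complex(real = 0), length(scales), n)
  norm0 <- pi^(-1 / 4)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- numeric(nz)
    pos <- omega > 0
    psi[pos] <- norm0 * sqrt(2 * pi * s / dt) * exp(-(s * omega[pos] - omega0)^2 / 2)
    wave <- fft(xh * psi, inverse = TRUE) / nz
    out[si, ] <- wave[seq_len(n)]
  }
  out
}

# Boxcar moving average along a vector with partial windows at the edges
# (normalized by the actual number of samples in the window). O(n) via
# cumulative sums.
boxcar_smooth <- function(v, half) {
  if (half < 1L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(1L, seq_len(n) - half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Smoothing operator for coherence: per-scale boxcar in time spanning one
# wavelet e-folding time (sqrt(2) * s) on each side of the position, then a
# boxcar over 7 adjacent scales (about half an octave at 12 voices).
# Applied identically to all three spectral fields; without enough
# averaging the coherence of independent noise is biased toward 1.
smooth_field <- function(M, fs, scales) {
  for (si in seq_len(nrow(M))) {
    half <- max(1L, round(sqrt(2) * scales[si] * fs))
    M[si, ] <- boxcar_smooth(M[si, ], half)
  }
  if (nrow(M) >= 3L) {
    Ms <- M
    for (ti in seq_len(ncol(M))) {
      Ms[, ti] <- boxcar_smooth(M[, ti], 3L)
    }
    M <- Ms
  }
  M
}

#' Magnitude-squared wavelet coherence
#'
#' Time-frequency-localized squared correlation of two signals:
#' `C(a, b) = |S(Cg* Cv)|^2 / (S(|Cg|^2) S(|Cv|^2))`, where `Cg`, `Cv` are
#' continuous wavelet transforms with the analytic Morlet wavelet
#' (center frequency 6) and `S` smooths over time (boxcar spanning one
#' e-folding time on each side, per scale) and over 7 adjacent scales
#' (about half an octave). The scale grid covers
#' roughly 0.5-30 Hz at 12 voices per octave; the low-frequency limit is
#' additionally bounded by `2 / duration`. The cone of influence marks
#' where edge effects contaminate the estimate.
#'
#' @param g,v [uniform_signal()]s with identical `fs` and length, at least
#'   4 s of data.
#' @param fmax upper frequency bound, Hz (capped below Nyquist).
#' @param voices scales per octave.
#' @return A `coherence_map` with `coherence` (scales x time, in `[0, 1]`),
#'   `freqs` (Hz, descending), `times` (s), `coi` (per-column boundary
#'   frequency: cells with `freq >= coi` are inside the cone and reliable),
#'   and `smoothing` descriptors.
#' @export
wavelet_coherence <- function(g, v, fmax = 30, voices = 12L) {
  stopifnot(inherits(g, "uniform_signal"), inherits(v, "uniform_signal"))
  if (!isTRUE(all.equal(g$fs, v$fs)) || length(g$values) != length(v$values)) {
    stop_scg("scg_alignment_error",
             "signals must share sampling rate and length")
  }
  fs <- g$fs
  n <- length(g$values)
  dur <- (n - 1) / fs
  if (dur < 4) stop_scg("scg_length_error", "need at least 4 s of data")
  omega0 <- 6
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  fhi <- min(fmax, 0.45 * fs)
  flo <- max(0.5, 2 / dur)
  s_min <- 1 / (fourier_factor * fhi)
  n_scales <- ceiling(voices * log2(fhi / flo)) + 1L
  scales <- s_min * 2^((seq_len(n_scales) - 1L) / voices)
  freqs <- 1 / (fourier_factor * scales)

  Cg <- morlet_cwt(g$values, fs, scales, omega0)
  Cv <- morlet_cwt(v$values, fs, scales, omega0)
  s_cross <- smooth_field(Conj(Cg) * Cv, fs, scales)
  s_g <- smooth_field(Mod(Cg)^2, fs, scales)
  s_v <- smooth_field(Mod(Cv)^2, fs, scales)
  denom <- s_g * s_v
  coh <- Mod(s_cross)^2 / pmax(denom, .Machine$double.xmin)
  coh <- matrix(pmin(coh, 1 + 1e-6), nrow = n_scales)

  times <- g$t0 + (seq_len(n) - 1) / fs
  edge_dist <- pmin(seq_len(n) - 1, n - seq_len(n)) / fs
  # valid scales satisfy sqrt(2) * s <= distance to the nearest edge
  coi <- ifelse(edge_dist > 0, sqrt(2) / (fourier_factor * edge_dist), Inf)

  structure(
    list(coherence = coh, freqs = freqs, times = times, coi = coi,
         smoothing = list(time = "boxcar, one e-folding time each side per scale",
                          scale = "boxcar over 7 adjacent scales"),
         fs = fs, omega0 = omega0),
    class = "coherence_map"
  )
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf(
    "<coherence_map> %d scales (%.2f-%.2f Hz) x %d times; mean in-cone %.3f\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    mean_coherence_in_coi(x)))
  invisible(x)
}

#' Mean coherence inside the cone of influence
#'
#' @param map a [wavelet_coherence()] result.
#' @return Mean of the coherence cells unaffected by edge effects.
#' @export
mean_coherence_in_coi <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  valid <- outer(map$freqs, map$coi, ">=")
  if (!any(valid)) return(NA_real_)
  mean(map$coherence[valid])
}

#' Write a coherence map as CSV matrix plus axis files
#'
#' @param map a [wavelet_coherence()] result.
#' @param prefix path prefix; writes `<prefix>_coherence.csv`,
#'   `<prefix>_freqs.csv`, `<prefix>_times.csv`, `<prefix>_coi.csv`.
#' @return The prefix, invisibly.
#' @export
write_coherence_csv <- function(map, prefix) {
  stopifnot(inherits(map, "coherence_map"))
  utils::write.table(map$coherence, paste0(prefix, "_coherence.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write.csv(data.frame(freq_hz = map$freqs), paste0(prefix, "_freqs.csv"),
            row.names = FALSE)
  write.csv(data.frame(time_s = map$times), paste0(prefix, "_times.csv"),
            row.names = FALSE)
  write.csv(data.frame(coi_freq_hz = map$coi), paste0(prefix, "_coi.csv"),
            row.names = FALSE)
  invisible(prefix)
}
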
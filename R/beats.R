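#' R-peak series
#'
#' @param indices 1-based sample indices of R peaks, strictly increasing.
#' @param fs sampling frequency of the underlying ECG, Hz.
#' @return An `r_peak_series` object.
#' @export
r_peak_series <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    stop_scg("scg_domain_error", "R-peak indices must be strictly increasing")
  }
  if (fs <= 0) stop_scg("scg_domain_error", "fs must be positive")
  structure(list(indices = indices, fs = as.numeric(fs)),
            class = "r_peak_series")
}

#' @export
print.r_peak_series <- function(x, ...) {
  cat(sprintf("<r_peak_series> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Times of the R peaks in seconds
#' @param rpeaks an [r_peak_series()].
#' @return Numeric vector of peak times (first sample of the record = 0 s).
#' @export
r_peak_times <- function(rpeaks) {
  stopifnot(inherits(rpeaks, "r_peak_series"))
  (rpeaks$indices - 1L) / rpeaks$fs
}

#' Pan-Tompkins QRS detection
#'
#' The classic chain: 5-15 Hz bandpass, differentiation, squaring, 150 ms
#' moving-window integration, then adaptive dual thresholds with a 200 ms
#' refractory period and a search-back pass for missed beats. Detected
#' positions are refined to the local maximum of the bandpassed ECG within
#' +/- 25 ms. Thresholds adapt multiplicatively, so detection is invariant
#' to amplitude scaling of the input.
#'
#' @param ecg a [uniform_signal()] with `fs >= 100` Hz and at least 2 s of
#'   data.
#' @return An [r_peak_series()] on the ECG's own sample grid.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "uniform_signal"))
  fs <- ecg$fs
  if (fs < 100) stop_scg("scg_domain_error", "ECG fs must be >= 100 Hz")
  if (signal_duration(ecg) < 2) {
    stop_scg("scg_length_error", "need at least 2 s of ECG")
  }
  if (sd(ecg$values) == 0) stop_scg("scg_no_beats_error", "flat ECG: no beats")
  xf <- bandpass(ecg, 5, 15)$values
  d <- c(0, diff(xf)) * fs
  sq <- d * d
  win <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2L))
  mwi[is.na(mwi)] <- 0
  n <- length(mwi)

  # candidate peaks of the integrated signal: the MWI envelope of one QRS is
  # a plateau with several local maxima, so keep only the tallest peak
  # within any refractory-length neighbourhood
  refractory <- round(0.2 * fs)
  cand <- find_peaks(mwi, min_distance = refractory)
  if (length(cand) == 0L) stop_scg("scg_no_beats_error", "no QRS candidates found")

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  noisy <- integer(0)   # rejected candidates, for search-back
  rr_hist <- numeric(0)

  for (p in cand) {
    if (length(accepted) > 0L && p - accepted[length(accepted)] < refractory) {
      next
    }
    if (mwi[p] > thr()) {
      # search-back happens implicitly: before accepting a peak much later
      # than expected, re-examine skipped candidates at half threshold
      if (length(rr_hist) >= 2L && length(accepted) >= 1L) {
        rr_avg <- mean(tail(rr_hist, 8L))
        gap <- p - accepted[length(accepted)]
        if (gap > 1.66 * rr_avg && length(noisy) > 0L) {
          inwin <- noisy[noisy > accepted[length(accepted)] + refractory &
                           noisy < p - refractory]
          if (length(inwin) > 0L) {
            best <- inwin[which.max(mwi[inwin])]
            if (mwi[best] > 0.5 * thr()) {
              rr_hist <- c(rr_hist, best - accepted[length(accepted)])
              accepted <- c(accepted, best)
              spki <- 0.25 * mwi[best] + 0.75 * spki
            }
          }
        }
      }
      if (length(accepted) > 0L) {
        rr_hist <- c(rr_hist, p - accepted[length(accepted)])
      }
      accepted <- c(accepted, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      noisy <- c(noisy, p)
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  if (length(accepted) == 0L) stop_scg("scg_no_beats_error", "no R peaks detected")

  # refine to the local maximum of the bandpassed ECG within +/- 25 ms
  half <- as.integer(round(0.025 * fs))
  refined <- vapply(accepted, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(xf[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  refined <- refined[c(TRUE, diff(refined) >= refractory)]
  r_peak_series(refined, fs)
}

#' Cut an SCG record into beat-aligned segments
#'
#' The average cardiac cycle length in samples, `n_c`, is the rounded mean
#' RR interval. Beat `i` occupies the window starting `floor(n_c/4)` samples
#' before its R peak and extending to a total length of exactly `n_c`
#' (one quarter cycle before the R wave, three quarters after). Beats whose
#' window leaves the record are dropped and listed.
#'
#' @param scg a [uniform_signal()] on the same grid as the R peaks.
#' @param rpeaks an [r_peak_series()] with matching `fs`.
#' @return A `beat_segmentation` with `n_c`, `segments` (matrix, one beat
#'   per row), `kept_beats` (indices into `rpeaks$indices`).
#' @export
segment_beats <- function(scg, rpeaks) {
  stopifnot(inherits(scg, "uniform_signal"), inherits(rpeaks, "r_peak_series"))
  if (!isTRUE(all.equal(scg$fs, rpeaks$fs))) {
    stop_scg("scg_alignment_error",
             "SCG (fs %g) and R peaks (fs %g) are not on the same grid",
             scg$fs, rpeaks$fs)
  }
  if (length(rpeaks$indices) < 2L) {
    stop_scg("scg_insufficient_beats_error",
             "need at least 2 R peaks to compute the cycle length")
  }
  n_c <- round(mean(diff(rpeaks$indices)))
  if (n_c < 4L) stop_scg("scg_domain_error", "cycle length n_c = %d too short", n_c)
  q <- floor(n_c / 4)
  n <- length(scg$values)
  starts <- rpeaks$indices - q
  ends <- starts + n_c - 1L
  keep <- which(starts >= 1L & ends <= n)
  if (length(keep) == 0L) {
    stop_scg("scg_insufficient_beats_error", "no beat window fits in the record")
  }
  seg <- t(vapply(keep, function(i) scg$values[starts[i]:ends[i]],
                  numeric(n_c)))
  structure(
    list(n_c = as.integer(n_c), segments = seg, kept_beats = keep,
         fs = scg$fs, dropped_beats = setdiff(seq_along(rpeaks$indices), keep)),
    class = "beat_segmentation"
  )
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf("<beat_segmentation> %d beats x %d samples (n_c), %d dropped\n",
              nrow(x$segments), x$n_c, length(x$dropped_beats)))
  invisible(x)
}

#' Ensemble average of beat segments
#'
#' Pointwise mean across beat-aligned segments; suppresses beat-to-beat
#' variability and uncorrelated noise by about `1/sqrt(n_beats)`.
#'
#' @param seg a [segment_beats()] result.
#' @return An `ensemble_waveform` with `values` (length `n_c`), `n_beats`,
#'   and `fs`.
#' @export
ensemble_average <- function(seg) {
  stopifnot(inherits(seg, "beat_segmentation"))
  if (nrow(seg$segments) < 1L) {
    stop_scg("scg_empty_error", "no segments to average")
  }
  structure(
    list(values = colMeans(seg$segments), n_beats = nrow(seg$segments),
         fs = seg$fs),
    class = "ensemble_waveform"
  )
}

#' @export
print.ensemble_waveform <- function(x, ...) {
  cat(sprintf("<ensemble_waveform> %d samples, mean of %d beats\n",
              length(x$values), x$n_beats))
  invisible(x)
}
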
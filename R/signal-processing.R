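#' Acceleration from displacement by second differencing
#'
#' Interior samples use the central second difference
#' `a[n] = (x[n+1] - 2 x[n] + x[n-1]) * fs^2`; the two endpoints replicate
#' their nearest interior value so the length is preserved. Millimeter input
#' is converted to meters, so the output is in m/s^2.
#'
#' @param disp a [uniform_signal()] in `"mm"` (or `"m"`).
#' @return A [uniform_signal()] in `"m/s2"` at the same rate.
#' @examples
#' d <- uniform_signal(seq(0, 1, by = 0.1)^2, fs = 1, units = "m")
#' displacement_to_acceleration(d)$values  # constant 2 on the interior
#' @export
displacement_to_acceleration <- function(disp) {
  stopifnot(inherits(disp, "uniform_signal"))
  x <- disp$values
  if (length(x) < 3L) {
    stop_scg("scg_length_error",
             "need at least 3 samples to differentiate, got %d", length(x))
  }
  scale <- switch(disp$units, mm = 1e-3, m = 1,
                  stop_scg("scg_units_error",
                           "displacement units must be 'mm' or 'm', got '%s'",
                           disp$units))
  n <- length(x)
  a <- numeric(n)
  a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * disp$fs^2
  a[1L] <- a[2L]
  a[n] <- a[n - 1L]
  uniform_signal(a * scale, fs = disp$fs, units = "m/s2", t0 = disp$t0)
}

#' Resample a signal to a new rate
#'
#' Samples are linearly interpolated onto the uniform target grid. When
#' upsampling, a zero-phase-compensated FIR lowpass at the source Nyquist
#' frequency (the lower of the two) is then applied on the new grid: it
#' rejects the spectral images that linear interpolation creates above the
#' source Nyquist and simultaneously equalizes the interpolation droop, so
#' band-limited content survives a round trip to a higher rate and back
#' within a fraction of a percent. Padding extrapolates the edge slope, so
#' constants and ramps pass through exactly. Signals fed to a lower rate
#' are assumed band-limited below the target Nyquist (every signal in this
#' pipeline is, by construction or by prior bandpass).
#'
#' @param sig a [uniform_signal()].
#' @param target_fs target sampling frequency, Hz (> 0).
#' @return A [uniform_signal()] at `target_fs` spanning the same duration
#'   (within one sample period).
#' @export
resample_to <- function(sig, target_fs) {
  stopifnot(inherits(sig, "uniform_signal"))
  if (target_fs <= 0) stop_scg("scg_domain_error", "target_fs must be positive")
  if (isTRUE(all.equal(target_fs, sig$fs))) return(sig)
  x <- sig$values
  n <- length(x)
  dur <- (n - 1L) / sig$fs
  m <- floor(dur * target_fs) + 1L
  tt <- (seq_len(m) - 1L) / target_fs
  y <- approx(x = (seq_len(n) - 1L) / sig$fs, y = x, xout = tt)$y
  if (target_fs > sig$fs) {
    nyq_s <- sig$fs / 2
    pass <- 0.885 * nyq_s              # equalized passband edge
    stopf <- sig$fs - pass             # first interpolation image of `pass`
    ntaps <- 2L * ceiling(1.65 * target_fs / (stopf - pass)) + 1L
    ntaps <- min(max(ntaps, 255L), 2501L)
    half <- (ntaps - 1L) %/% 2L
    droop <- function(f) {
      z <- pi * f / sig$fs
      ifelse(f == 0, 1, (sin(z) / z)^2)  # linear-interp frequency response
    }
    fpass <- seq(0, pass, length.out = 60L)
    ftrans <- seq(pass, stopf, length.out = 15L)[-1L]
    fg <- c(fpass, ftrans, stopf * 1.001, target_fs / 2)
    mg <- c(1 / droop(fpass),
            (1 / droop(pass)) * 0.5 * (1 + cos(pi * seq(0, 1, length.out = 15L)[-1L])),
            0, 0)
    b <- signal::fir2(ntaps - 1L, fg / (target_fs / 2), mg)
    b <- b / sum(b)                    # exact unit DC gain
    slope1 <- y[2L] - y[1L]
    slope2 <- y[m] - y[m - 1L]
    yp <- c(y[1L] + slope1 * (-half:-1L), y, y[m] + slope2 * (1:half))
    yf <- stats::filter(yp, b, method = "convolution", sides = 1L)
    y <- as.numeric(yf[(ntaps):(ntaps + m - 1L)])  # group delay compensated
  }
  uniform_signal(y, fs = target_fs, units = sig$units, t0 = sig$t0)
}

#' Zero-phase Butterworth bandpass
#'
#' A fourth-order Butterworth bandpass (two poles per band edge) applied
#' forward-backward, so the net phase is zero and beat timing is preserved
#' across instruments.
#'
#' @param sig a [uniform_signal()].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return Filtered [uniform_signal()], same length, rate and units.
#' @export
bandpass <- function(sig, lo, hi) {
  stopifnot(inherits(sig, "uniform_signal"))
  nyq <- sig$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop_scg("scg_domain_error",
             "band edges must satisfy 0 < lo < hi < fs/2 (got %g, %g at fs %g)",
             lo, hi, sig$fs)
  }
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, sig$values)
  uniform_signal(y, fs = sig$fs, units = sig$units, t0 = sig$t0)
}

#' Detect synchronization taps in an audio channel
#'
#' Microphone taps recorded at the start and end of each acquisition mark
#' common events on both clocks. A short-time energy envelope (20 ms
#' window) is thresholded at `k` times its median; each threshold-crossing
#' onset is one event, and events closer than `min_gap_s` are merged.
#'
#' @param audio a [uniform_signal()], at least 0.5 s long.
#' @param threshold_factor `k`, the envelope threshold in units of the
#'   median envelope.
#' @param min_gap_s events closer than this are merged into the first.
#' @return A `sync_events` object with `tap_times` (seconds, on the
#'   channel's own clock) and `detection_threshold`.
#' @export
detect_taps <- function(audio, threshold_factor = 8, min_gap_s = 0.5) {
  stopifnot(inherits(audio, "uniform_signal"))
  if (signal_duration(audio) < 0.5) {
    stop_scg("scg_length_error", "audio must be at least 0.5 s long")
  }
  win <- max(1L, round(0.02 * audio$fs))
  e2 <- stats::filter(audio$values^2, rep(1 / win, win), sides = 2L)
  env <- sqrt(pmax(as.numeric(e2), 0))
  env[is.na(env)] <- 0
  med <- median(env)
  thr <- threshold_factor * med
  above <- env > thr & env > 0
  if (!any(above)) {
    stop_scg("scg_no_taps_error", "no taps found above %g x median envelope",
             threshold_factor)
  }
  onset <- which(above & !c(FALSE, above[-length(above)]))
  times <- audio$t0 + (onset - 1L) / audio$fs
  # merge runs: keep first event of each cluster
  merged <- numeric(0)
  for (tm in times) {
    if (length(merged) == 0L || tm - merged[length(merged)] >= min_gap_s) {
      merged <- c(merged, tm)
    }
  }
  structure(list(tap_times = merged, detection_threshold = thr),
            class = "sync_events")
}

#' @export
print.sync_events <- function(x, ...) {
  cat(sprintf("<sync_events> %d taps at [%s] s\n", length(x$tap_times),
              paste(sprintf("%.3f", x$tap_times), collapse = ", ")))
  invisible(x)
}

#' Align two independently clocked recordings via shared taps
#'
#' The first and last tap on each side are assumed to be the same physical
#' events; the affine map `t_dst = offset + drift * t_src` through those two
#' anchors synchronizes the clocks exactly at the anchors.
#'
#' @param src,dst `sync_events` from [detect_taps()] (or built manually),
#'   each with at least 2 events.
#' @return A `clock_map` with fields `offset` (s) and `drift`
#'   (dimensionless, sanity-checked to `[0.9, 1.1]`).
#' @examples
#' src <- structure(list(tap_times = c(1, 29)), class = "sync_events")
#' dst <- structure(list(tap_times = c(2.5, 30.5)), class = "sync_events")
#' align_clocks(src, dst)  # offset 1.5, drift 1
#' @export
align_clocks <- function(src, dst) {
  for (ev in list(src, dst)) {
    if (length(ev$tap_times) < 2L) {
      stop_scg("scg_insufficient_anchors_error",
               "need at least 2 taps on each side to align clocks")
    }
  }
  s1 <- src$tap_times[1L]; s2 <- src$tap_times[length(src$tap_times)]
  d1 <- dst$tap_times[1L]; d2 <- dst$tap_times[length(dst$tap_times)]
  drift <- (d2 - d1) / (s2 - s1)
  if (!is.finite(drift) || drift < 0.9 || drift > 1.1) {
    stop_scg("scg_sanity_error",
             "clock drift %.4f outside the plausible range [0.9, 1.1]", drift)
  }
  structure(list(offset = d1 - drift * s1, drift = drift), class = "clock_map")
}

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf("<clock_map> t_dst = %.6f + %.8f * t_src\n", x$offset, x$drift))
  invisible(x)
}

#' Map times or signals onto the destination clock
#'
#' @param map a [align_clocks()] result.
#' @param t numeric vector of source-clock times.
#' @return `map_time()`: the corresponding destination-clock times.
#' @export
map_time <- function(map, t) {
  stopifnot(inherits(map, "clock_map"))
  map$offset + map$drift * t
}
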
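# Local maxima with a minimum topographic prominence and minimum spacing.
# Prominence of a peak: its height minus the higher of the two valley
# minima separating it from the nearest higher ground on each side.
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  if (min_prominence <= 0) {
    keep <- cand
    if (length(keep) <= 1L || min_distance <= 1L) return(sort(keep))
    ord <- keep[order(x[keep], decreasing = TRUE)]
    sel <- integer(0)
    for (p in ord) {
      if (all(abs(sel - p) >= min_distance)) sel <- c(sel, p)
    }
    return(sort(sel))
  }
  prom <- vapply(cand, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) { lmin <- min(lmin, x[i]); i <- i - 1L }
    if (i < 1L) lmin <- min(x[1:p])
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) { rmin <- min(rmin, x[i]); i <- i + 1L }
    if (i > n) rmin <- min(x[p:n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L || min_distance <= 1L) return(sort(keep))
  # greedy by height: taller peaks suppress neighbours within min_distance
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (p in ord) {
    if (all(abs(sel - p) >= min_distance)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Beat-to-beat heart rate from R peaks
#'
#' One rate per consecutive R-R interval: `bpm_i = 60 / (t_{i+1} - t_i)`,
#' timestamped at the interval midpoint.
#'
#' @param rpeaks an [r_peak_series()] with at least 2 peaks.
#' @return An `hr_series` with `times` (s), `bpm`, `source = "ecg"`.
#' @examples
#' rp <- r_peak_series(c(1, 4001, 8001), fs = 5000)
#' hr_from_r_peaks(rp)$bpm  # 75, 75
#' @export
hr_from_r_peaks <- function(rpeaks) {
  stopifnot(inherits(rpeaks, "r_peak_series"))
  if (length(rpeaks$indices) < 2L) {
    stop_scg("scg_insufficient_beats_error",
             "need at least 2 R peaks for a rate")
  }
  tt <- r_peak_times(rpeaks)
  bpm <- 60 / diff(tt)
  structure(
    list(times = (head(tt, -1L) + tail(tt, -1L)) / 2, bpm = bpm,
         source = "ecg"),
    class = "hr_series"
  )
}

#' Heart rate from a vision-based SCG signal
#'
#' A deliberately simple estimator: zero-phase bandpass at the cardiac
#' fundamental (0.7-1.5 Hz), then peak picking with a minimum separation of
#' 0.4 s (a 150 bpm ceiling) and a prominence of at least one quarter of
#' the filtered signal's standard deviation; rates follow from consecutive
#' peak intervals. Peaks within one low-cutoff period of either record edge
#' are discarded, since filter startup transients shift them. Known behaviour of this class of estimator: rates above
#' ~81 bpm tend to be slightly underestimated and rates below 60 bpm show
#' wider dispersion; no correction is applied.
#'
#' @param scg_v a [uniform_signal()], at least 5 s long, `fs >= 10` Hz.
#' @param band bandpass edges in Hz.
#' @return An `hr_series` with `source = "scg"`.
#' @export
hr_from_scg <- function(scg_v, band = c(0.7, 1.5)) {
  stopifnot(inherits(scg_v, "uniform_signal"))
  if (signal_duration(scg_v) < 5) {
    stop_scg("scg_insufficient_beats_error",
             "need at least 5 s of SCG for a rate estimate")
  }
  if (scg_v$fs < 10) stop_scg("scg_domain_error", "SCG fs must be >= 10 Hz")
  filt <- bandpass(scg_v, band[1L], band[2L])$values
  pk <- find_peaks(filt, min_distance = round(0.4 * scg_v$fs),
                   min_prominence = 0.25 * sd(filt))
  # drop peaks inside the filter's edge transients (one low-cutoff period
  # at each end), where zero-phase IIR startup shifts peak positions
  edge <- (1 / band[1L]) * scg_v$fs
  n <- length(filt)
  pk <- pk[pk > edge & pk <= n - edge]
  if (length(pk) < 2L) {
    stop_scg("scg_insufficient_beats_error",
             "fewer than 2 cardiac peaks after filtering")
  }
  tt <- scg_v$t0 + (pk - 1L) / scg_v$fs
  structure(
    list(times = (head(tt, -1L) + tail(tt, -1L)) / 2, bpm = 60 / diff(tt),
         source = "scg"),
    class = "hr_series"
  )
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d intervals from %s, mean %.1f bpm\n",
              length(x$bpm), x$source, mean(x$bpm)))
  invisible(x)
}

#' Mean heart rate of a series
#' @param hr an `hr_series`.
#' @return Mean bpm across intervals.
#' @export
mean_hr <- function(hr) {
  stopifnot(inherits(hr, "hr_series"))
  mean(hr$bpm)
}
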
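#' Uniformly sampled one-dimensional signal
#'
#' Container for displacement, acceleration, ECG and audio channels: a
#' numeric sample vector plus sampling frequency, physical units and start
#' time. All higher-level operations in the package accept and return this
#' class.
#'
#' @param values numeric vector of samples; must be finite, length >= 2.
#' @param fs sampling frequency in Hz (> 0).
#' @param units free-text unit label, e.g. `"mm"`, `"m/s2"`, `"mV"`, `"a.u."`.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `uniform_signal` with fields `values`, `fs`,
#'   `units`, `t0`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 2 * seq(0, 1, by = 0.01)), fs = 100)
#' signal_duration(s)
#' @export
uniform_signal <- function(values, fs, units = "a.u.", t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop_scg("scg_length_error", "uniform_signal needs at least 2 samples, got %d",
             length(values))
  }
  if (!all(is.finite(values))) {
    stop_scg("scg_domain_error", "uniform_signal values must all be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_scg("scg_domain_error", "sampling frequency must be a positive number")
  }
  structure(
    list(values = values, fs = as.numeric(fs), units = as.character(units),
         t0 = as.numeric(t0)),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz [%s], t0 = %g s (%.3f s)\n",
              length(x$values), x$fs, x$units, x$t0, signal_duration(x)))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Duration and time axis of a uniform signal
#'
#' @param sig a [uniform_signal()].
#' @return `signal_duration()`: span between first and last sample in
#'   seconds. `signal_times()`: vector of sample times in seconds.
#' @export
signal_duration <- function(sig) {
  stopifnot(inherits(sig, "uniform_signal"))
  (length(sig$values) - 1L) / sig$fs
}

#' @rdname signal_duration
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "uniform_signal"))
  sig$t0 + (seq_along(sig$values) - 1L) / sig$fs
}

#' Read and write signals as two-column CSV
#'
#' The on-disk format is `time_s,value` with a `# fs=<Hz> units=<units>`
#' comment line, so channels survive a round trip with their metadata.
#'
#' @param sig a [uniform_signal()].
#' @param path file path.
#' @return `write_signal_csv()` returns `path` invisibly;
#'   `read_signal_csv()` returns a [uniform_signal()].
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "uniform_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g units=%s t0=%.10g", sig$fs, sig$units, sig$t0),
             con)
  write.csv(data.frame(time_s = signal_times(sig), value = sig$values),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  header <- readLines(path, n = 1L)
  fs <- NA_real_; units <- "a.u."; t0 <- 0
  if (startsWith(header, "#")) {
    fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", header))
    units <- sub(".*units=([^ ]+).*", "\\1", header)
    t0v <- suppressWarnings(as.numeric(sub(".*t0=([0-9.eE+-]+).*", "\\1", header)))
    if (is.finite(t0v)) t0 <- t0v
  }
  d <- read.csv(path, comment.char = "#")
  if (!is.finite(fs)) {
    dt <- diff(d$time_s)
    fs <- 1 / median(dt)
    t0 <- d$time_s[1L]
  }
  uniform_signal(d$value, fs = fs, units = units, t0 = t0)
}
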
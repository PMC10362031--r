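#' Pearson correlation between equal-length waveforms
#'
#' @param a,b numeric vectors of equal length (>= 3), neither constant.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L) {
    stop_scg("scg_length_error", "inputs must be equal length >= 3")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_scg("scg_undefined_correlation_error",
             "correlation undefined for constant input")
  }
  cor(a, b)
}

#' Band-constrained dynamic time warping
#'
#' Aligns two scalar series by a monotone warping path with steps down,
#' right and diagonal, minimizing the accumulated local cost `|a_i - b_j|`.
#' The path is restricted to a corridor of half-width
#' `ceiling(band_fraction * max(length(a), length(b)))` cells around the
#' straight-line fit between the endpoints (a Sakoe-Chiba-style band,
#' measured along either index axis so that the constraint is symmetric in
#' the two series).
#'
#' @param a,b numeric vectors, both non-empty.
#' @param band_fraction corridor half-width as a fraction of the longer
#'   series; the conventional default is 5%.
#' @return A `dtw_result` with `distance`, `path` (two-column matrix of
#'   1-based index pairs from `(1, 1)` to `(n, m)`), and `band_fraction`.
#' @examples
#' dtw_alignment(c(0, 0, 1), c(0, 1), band_fraction = 1)$distance  # 0
#' @export
dtw_alignment <- function(a, b, band_fraction = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stop_scg("scg_domain_error", "inputs must be non-empty")
  w <- max(1L, ceiling(band_fraction * max(n, m)))
  if (n == 1L || m == 1L) {
    # degenerate: the path is forced through every cell of the single row
    # or column
    lo <- rep(1L, n); hi <- rep(m, n)
  } else {
    # corridor around the straight-line fit, measured along either axis so
    # the band is symmetric under argument swap: cell (i, j) is admissible
    # when |j - j*(i)| <= w or |i - i*(j)| <= w
    jstar <- 1 + (seq_len(n) - 1) * (m - 1) / (n - 1)
    slope <- (m - 1) / (n - 1)
    lo <- pmax(1, ceiling(pmin(jstar - w, 1 + (seq_len(n) - 1 - w) * slope)))
    hi <- pmin(m, floor(pmax(jstar + w, 1 + (seq_len(n) - 1 + w) * slope)))
  }
  if (any(hi < lo) || any(lo[-1L] > hi[-n] + 1L)) {
    stop_scg("scg_infeasible_band_error",
             "band of half-width %d cannot connect the corners for lengths %d, %d",
             w, n, m)
  }
  width <- max(hi - lo + 1L)
  INF <- Inf
  D <- matrix(INF, n, width)       # D[i, j - lo[i] + 1]
  # row 1: only left steps
  c1 <- abs(a[1L] - b[lo[1L]:hi[1L]])
  D[1L, seq_len(hi[1L] - lo[1L] + 1L)] <- cumsum(c1)
  if (n >= 2L) for (i in 2L:n) {
    js <- lo[i]:hi[i]
    k <- seq_along(js)
    cost <- abs(a[i] - b[js])
    # predecessor values from row i-1, padded with Inf outside its band
    prev <- function(j) {
      v <- rep(INF, length(j))
      ok <- j >= lo[i - 1L] & j <= hi[i - 1L]
      v[ok] <- D[i - 1L, j[ok] - lo[i - 1L] + 1L]
      v
    }
    up <- prev(js)
    diag <- prev(js - 1L)
    m1 <- cost + pmin(up, diag)
    # fold in the within-row left step: d[k] = min(m1[k], cost[k] + d[k-1])
    # equals Csum[k] + cummin(m1 - Csum) with Csum the prefix sums of cost
    csum <- cumsum(cost)
    d <- csum + cummin(m1 - csum)
    D[i, k] <- d
  }
  distance <- D[n, m - lo[n] + 1L]

  # backtrack by predecessor argmin (diagonal preferred on ties)
  path <- matrix(NA_integer_, n + m, 2L)
  pk <- 1L
  i <- n; j <- m
  path[pk, ] <- c(i, j)
  getD <- function(i, j) {
    if (i < 1L || j < lo[i] || j > hi[i]) return(INF)
    D[i, j - lo[i] + 1L]
  }
  while (i > 1L || j > 1L) {
    cand <- c(diag = getD(i - 1L, j - 1L), up = getD(i - 1L, j),
              left = getD(i, j - 1L))
    pick <- names(cand)[which.min(cand)]
    if (pick == "diag") { i <- i - 1L; j <- j - 1L }
    else if (pick == "up") i <- i - 1L
    else j <- j - 1L
    pk <- pk + 1L
    path[pk, ] <- c(i, j)
  }
  path <- path[pk:1L, , drop = FALSE]
  colnames(path) <- c("i", "j")
  structure(list(distance = distance, path = path, band_fraction = band_fraction),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g, path length %d, band %.3g\n",
              x$distance, nrow(x$path), x$band_fraction))
  invisible(x)
}

#' DTW-based similarity index between ensemble waveforms
#'
#' `S = (M - D) / M`, where `D` is the band-constrained DTW distance
#' between the gold-standard and vision-based ensemble averages, and the
#' normalizer `M` is the maximum absolute value of the gold-standard
#' ensemble multiplied by the segment length `n_c`. Values outside `[0, 1]`
#' are flagged (`out_of_range`), never clamped.
#'
#' @param gold,vision [ensemble_average()] results (or plain numeric
#'   vectors) of the same length.
#' @param band_fraction passed to [dtw_alignment()].
#' @return A `similarity_score` with `s`, `m`, `d`, `out_of_range`.
#' @export
similarity_index <- function(gold, vision, band_fraction = 0.05) {
  g <- if (inherits(gold, "ensemble_waveform")) gold$values else as.numeric(gold)
  v <- if (inherits(vision, "ensemble_waveform")) vision$values else as.numeric(vision)
  if (length(g) != length(v)) {
    stop_scg("scg_length_error", "ensembles must have equal length (n_c)")
  }
  n_c <- length(g)
  M <- max(abs(g)) * n_c
  if (M == 0) {
    stop_scg("scg_zero_normalizer_error",
             "gold-standard ensemble is identically zero; normalizer undefined")
  }
  D <- dtw_alignment(g, v, band_fraction)$distance
  s <- (M - D) / M
  structure(
    list(s = s, m = M, d = D, out_of_range = (s < 0 || s > 1)),
    class = "similarity_score"
  )
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> S = %.4f (M = %.4g, D = %.4g)%s\n",
              x$s, x$m, x$d, if (x$out_of_range) " [outside [0,1]]" else ""))
  invisible(x)
}

#' Time lag between two signals by normalized cross-correlation
#'
#' The lag maximizing the cross-correlation over `[-max_lag, max_lag]`.
#' Positive lag means `b` trails `a`.
#'
#' @param a,b [uniform_signal()]s at the same rate.
#' @param max_lag search half-range, seconds.
#' @return Lag in seconds.
#' @export
estimate_lag <- function(a, b, max_lag = 0.5) {
  stopifnot(inherits(a, "uniform_signal"), inherits(b, "uniform_signal"))
  if (!isTRUE(all.equal(a$fs, b$fs))) {
    stop_scg("scg_alignment_error", "signals must share a sampling rate")
  }
  fs <- a$fs
  L <- round(max_lag * fs)
  if (min(length(a$values), length(b$values)) < 2L * L) {
    stop_scg("scg_length_error",
             "signals must overlap by at least twice the maximum lag")
  }
  if (sd(a$values) == 0 || sd(b$values) == 0) {
    stop_scg("scg_undefined_lag_error", "lag undefined for constant input")
  }
  x <- a$values - mean(a$values)
  y <- b$values - mean(b$values)
  n <- max(length(x), length(y))
  nz <- 2^ceiling(log2(n + L + 1L))
  X <- fft(c(x, rep(0, nz - length(x))))
  Y <- fft(c(y, rep(0, nz - length(y))))
  # cc[k] = sum_t x[t] y[t + k]; positive k means b trails a
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / nz
  lags <- -L:L
  vals <- cc[ifelse(lags >= 0, lags + 1L, nz + lags + 1L)]
  lags[which.max(vals)] / fs
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias) and the limits of agreement `bias +/- 1.96 SD`
#' of the paired differences.
#'
#' @param a,b numeric vectors of paired measurements, equal length >= 2.
#' @return An `agreement_stats` with `bias`, `loa_low`, `loa_high`, `sd`,
#'   `n`.
#' @examples
#' bland_altman(c(70, 80), c(72, 78))
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L) {
    stop_scg("scg_insufficient_pairs_error",
             "need at least 2 pairs of equal length")
  }
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd = s, n = length(d)),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> bias %.4g, LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
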
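test_that("second differencing is exact on polynomials and analytic on tones", {
  # affine displacement has zero acceleration
  ramp <- uniform_signal(0.5 * (0:20), fs = 10, units = "mm")
  expect_equal(displacement_to_acceleration(ramp)$values, rep(0, 21))

  # central difference is exact on quadratics: x = n^2 (m), fs = 1 -> a = 2
  quad <- uniform_signal((0:10)^2, fs = 1, units = "m")
  a <- displacement_to_acceleration(quad)
  expect_equal(a$values[2:10], rep(2, 9))
  expect_identical(a$units, "m/s2")
  expect_equal(a$values[1], a$values[2])    # endpoint replication

  # 1 mm sinusoid at 10 Hz sampled at 5000 Hz: amplitude (2*pi*10)^2 mm/s^2
  s <- tone(10, 2, 5000, amp = 1, units = "mm")
  acc <- displacement_to_acceleration(s)
  expect_equal(max(abs(acc$values)), (2 * pi * 10)^2 * 1e-3, tolerance = 0.01)

  expect_error(displacement_to_acceleration(
    uniform_signal(c(1, 2), fs = 10, units = "mm")), class = "scg_length_error")
})

test_that("second differencing is a linear operator", {
  set.seed(20)
  x <- uniform_signal(rnorm(100), 50, units = "mm")
  y <- uniform_signal(rnorm(100), 50, units = "mm")
  mix <- uniform_signal(2.5 * x$values - 1.25 * y$values, 50, units = "mm")
  expect_equal(displacement_to_acceleration(mix)$values,
               2.5 * displacement_to_acceleration(x)$values -
                 1.25 * displacement_to_acceleration(y)$values,
               tolerance = 1e-12)
})

test_that("resampling preserves constants, ramps, tone amplitude and phase", {
  cst <- uniform_signal(rep(2, 60), 60)
  up <- resample_to(cst, 5000)
  expect_equal(up$values, rep(2, length(up$values)), tolerance = 1e-12)

  ramp <- uniform_signal(seq(0, 1, length.out = 61), 60)
  upr <- resample_to(ramp, 5000)
  expect_equal(upr$values[1], 0, tolerance = 1e-9)
  expect_equal(upr$values[length(upr$values)], 1, tolerance = 1e-9)

  s <- tone(5, 2, 60)
  rs <- resample_to(s, 5000)
  tt <- signal_times(rs)
  mid <- tt > 0.3 & tt < 1.7
  expect_equal(max(abs(rs$values[mid])), 1, tolerance = 0.01)
  # phase: cross-correlate against the analytic tone; best lag under 1 ms
  ref <- sin(2 * pi * 5 * tt)
  ks <- -10:10
  cc <- vapply(ks, function(k) sum(rs$values[which(mid)] * ref[which(mid) + k]),
               numeric(1))
  expect_lt(abs(ks[which.max(cc)]) / 5000, 0.001)
})

test_that("a 60 -> 5000 -> 60 Hz round trip preserves band-limited content
           within 1% RMS", {
  x <- with_seed_values <- local({
    set.seed(21)
    n <- 600
    t <- (0:(n - 1)) / 60
    rowSums(sapply(c(1.3, 4.7, 11, 18, 24.5), function(f)
      sin(2 * pi * f * t + f)))
  })
  s0 <- uniform_signal(x, 60)
  back <- resample_to(resample_to(s0, 5000), 60)
  n <- min(length(back$values), length(x))
  err <- sqrt(mean((back$values[1:n] - x[1:n])^2)) / sqrt(mean(x^2))
  expect_lt(err, 0.01)
})

test_that("bandpass rejects DC, passes mid-band tones, is nearly idempotent,
           and guards the Nyquist limit", {
  # the 1 Hz high-pass edge has a ~1 s transient at each end; judge DC
  # rejection over the middle of a 10 s record
  dc <- uniform_signal(rep(1, 20000), 2000)
  out <- bandpass(dc, 1, 30)
  mid <- 6000:14000
  expect_lt(max(abs(out$values[mid])), 1e-3)

  s <- tone(10, 4, 5000)
  f <- bandpass(s, 1, 30)
  tt <- signal_times(f)
  sel <- tt > 1 & tt < 3
  expect_equal(max(abs(f$values[sel])), 1, tolerance = 0.05)

  twice <- bandpass(f, 1, 30)
  rel <- sqrt(mean((twice$values[sel] - f$values[sel])^2)) /
    sqrt(mean(f$values[sel]^2))
  expect_lt(rel, 0.01)

  expect_error(bandpass(s, 1, 3000), class = "scg_domain_error")
})

test_that("tap detection finds isolated impulses and orders multiple events", {
  fs <- 8000
  x <- numeric(fs * 4)
  x[fs * 1 + 1] <- 1  # impulse at 1.000 s
  taps <- detect_taps(uniform_signal(x, fs))
  expect_length(taps$tap_times, 1)
  expect_equal(taps$tap_times, 1.0, tolerance = 0.025)

  y <- numeric(fs * 6)
  y[fs * 1 + 1] <- 1
  y[fs * 5 + 1] <- 0.8
  taps2 <- detect_taps(uniform_signal(y, fs))
  expect_length(taps2$tap_times, 2)
  expect_true(all(diff(taps2$tap_times) > 0))
  expect_equal(taps2$tap_times, c(1, 5), tolerance = 0.025)

  expect_error(detect_taps(uniform_signal(numeric(fs), fs)),
               class = "scg_no_taps_error")
})

test_that("clock alignment solves the two-point map and enforces sanity", {
  ev <- function(t) structure(list(tap_times = t), class = "sync_events")
  m <- align_clocks(ev(c(1, 29)), ev(c(2.5, 30.5)))
  expect_equal(m$offset, 1.5)
  expect_equal(m$drift, 1)

  ident <- align_clocks(ev(c(0.8, 31.2)), ev(c(0.8, 31.2)))
  expect_equal(ident$offset, 0)
  expect_equal(ident$drift, 1)

  expect_error(align_clocks(ev(c(0, 10)), ev(c(0, 20))),
               class = "scg_sanity_error")
  expect_error(align_clocks(ev(1), ev(c(1, 2))),
               class = "scg_insufficient_anchors_error")

  # anchors are mapped exactly for arbitrary admissible tap pairs
  set.seed(22)
  for (i in 1:20) {
    src <- sort(runif(2, 0, 100))
    drift <- runif(1, 0.95, 1.05)
    off <- runif(1, -5, 5)
    dst <- off + drift * src
    mm <- align_clocks(ev(src), ev(dst))
    expect_lt(max(abs(map_time(mm, src) - dst)), 1e-9)
  }
})
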
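test_that("generators are pure functions of their parameters and seed", {
  w1 <- make_scg_waveform(72, 4, 500, seed = 70)
  w2 <- make_scg_waveform(72, 4, 500, seed = 70)
  expect_identical(w1$values, w2$values)
  w3 <- make_scg_waveform(72, 4, 500, seed = 71)
  expect_false(identical(w1$values, w3$values))

  e1 <- make_synthetic_ecg(75, 6, 500, snr_db = 10, seed = 70)
  e2 <- make_synthetic_ecg(75, 6, 500, snr_db = 10, seed = 70)
  expect_identical(e1$ecg$values, e2$ecg$values)
  expect_identical(e1$rpeaks$indices, e2$rpeaks$indices)

  z <- uniform_signal(rep(0, 30), 60, units = "mm")
  s1 <- render_video(z, z, 0.1, 60, texture_seed = 70)
  s2 <- render_video(z, z, 0.1, 60, texture_seed = 70)
  expect_identical(s1$frames$frames, s2$frames$frames)
})

test_that("the cardiac waveform is periodic at the programmed rate", {
  fs <- 500
  w <- make_scg_waveform(60, 10, fs, seed = 72)
  x <- w$values - mean(w$values)
  ac <- vapply(1:(2 * fs), function(k) {
    n <- length(x) - k
    sum(x[1:n] * x[(k + 1):(k + n)]) / n
  }, numeric(1))
  # strongest off-zero autocorrelation peak sits at one cycle (1.0 s)
  expect_equal(which.max(ac) / fs, 1.0, tolerance = 0.02)
})

test_that("waveform spectral energy above 30 Hz is below 1%", {
  for (hr in c(48, 72, 150)) {
    w <- make_scg_waveform(hr, 8, 500, seed = 73)
    x <- w$values - mean(w$values)
    sp <- Mod(fft(x))^2
    n <- length(x)
    freqs <- (0:(n - 1)) * 500 / n
    half <- freqs <= 250
    hi <- half & freqs > 30
    expect_lt(sum(sp[hi]) / sum(sp[half]), 0.01)
  }
})

test_that("waveform rejects out-of-range rates and low frame rates", {
  expect_error(make_scg_waveform(20, 5, 500), class = "scg_domain_error")
  expect_error(make_scg_waveform(200, 5, 500), class = "scg_domain_error")
  expect_error(make_scg_waveform(70, 5, 60), class = "scg_domain_error")
})

test_that("rendering with zero motion repeats frame 1 exactly", {
  z <- uniform_signal(rep(0, 20), 60, units = "mm")
  sc <- render_video(z, z, 0.1, 60, texture_seed = 74)
  for (k in 2:length(sc$frames$frames)) {
    expect_identical(sc$frames$frames[[k]], sc$frames$frames[[1]])
  }
})

test_that("a constant one-pixel displacement shifts the patch by one column", {
  dx <- c(0, 1)  # px
  wf <- uniform_signal(dx * 0.1, 60, units = "mm")
  z <- uniform_signal(c(0, 0), 60, units = "mm")
  sc <- render_video(wf, z, 0.1, 60, texture_seed = 75)
  f1 <- sc$frames$frames[[1]]
  f2 <- sc$frames$frames[[2]]
  roi <- sc$suggested_roi  # (x0, y0, w, h), 0-based
  r <- (roi[2] + 1):(roi[2] + roi[4])
  c1 <- (roi[1] + 1):(roi[1] + roi[3])
  expect_equal(f2[r, c1 + 1], f1[r, c1], tolerance = 1e-12)
})

test_that("motion beyond the guard margin is a render-bounds error", {
  huge <- uniform_signal(c(0, 3), 60, units = "mm")  # 30 px at 0.1 mm/px
  z <- uniform_signal(c(0, 0), 60, units = "mm")
  expect_error(render_video(huge, z, 0.1, 60, texture_seed = 76),
               class = "scg_render_bounds_error")
})

test_that("clean synthetic ECG carries the expected beat count and spacing", {
  gen <- make_synthetic_ecg(75, 10, 500, seed = 77)
  n <- length(gen$rpeaks$indices)
  expect_true(n %in% c(12L, 13L))
  expect_equal(diff(r_peak_times(gen$rpeaks)),
               rep(0.8, n - 1), tolerance = 1 / 500)
})

test_that("scene generation is reproducible end to end", {
  s1 <- make_synthetic_scene(hr_bpm = 66, duration = 2, seed = 78)
  s2 <- make_synthetic_scene(hr_bpm = 66, duration = 2, seed = 78)
  expect_identical(s1$frames$frames, s2$frames$frames)
  expect_identical(s1$truth_acceleration$x$values, s2$truth_acceleration$x$values)
  expect_identical(s1$truth_ecg$values, s2$truth_ecg$values)
})
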
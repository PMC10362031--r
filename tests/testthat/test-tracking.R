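test_that("extract_template crops exactly and validates its preconditions", {
  set.seed(1)
  fr <- matrix(runif(100 * 120), 100, 120)  # 120 wide, 100 high
  fs <- frame_sequence(list(fr), 60)
  tpl <- extract_template(fs, c(10, 20, 64, 64))
  expect_identical(tpl$patch, fr[21:84, 11:74])
  expect_equal(tpl$coords$x[1, 1], 10)
  expect_equal(tpl$coords$y[1, 1], 20)

  expect_error(extract_template(fs, c(100, 0, 64, 64)), class = "scg_bounds_error")
  expect_error(extract_template(fs, c(0, 0, 4, 64)), class = "scg_bounds_error")

  flat <- frame_sequence(list(matrix(0.5, 64, 64)), 60)
  expect_error(extract_template(flat, c(0, 0, 32, 32)),
               class = "scg_untrackable_error")
})

test_that("warp_sample is the identity at u = 0, exact on integer shifts and
           on linear ramps at half-pixel offsets", {
  set.seed(2)
  fr <- matrix(runif(40 * 40), 40, 40)
  fs <- frame_sequence(list(fr), 60)
  tpl <- extract_template(fs, c(8, 8, 16, 16))

  expect_equal(warp_sample(fr, c(0, 0), tpl$coords), tpl$patch)
  # integer shift (3, -2): sampled at columns +3, rows -2
  shifted <- warp_sample(fr, c(3, -2), tpl$coords)
  expect_equal(shifted, fr[(9 - 2):(24 - 2), (9 + 3):(24 + 3)])
  # bilinear interpolation is exact on a horizontal linear ramp
  ramp <- matrix(rep(0:39, each = 40), 40, 40)
  half <- warp_sample(ramp, c(0.5, 0), tpl$coords)
  expect_equal(half, tpl_ramp <- (ramp[9:24, 9:24] + ramp[9:24, 10:25]) / 2)
  # leaving the frame raises the out-of-view signal
  expect_error(warp_sample(fr, c(30, 0), tpl$coords),
               class = "scg_out_of_view_error")
})

test_that("solve_warp_increment returns a zero step at the optimum, recovers a
           0.3 px shift in one step on smooth texture, and rejects flat frames", {
  # frame equals the template placed at offset u -> residual identically zero
  set.seed(3)
  fr <- matrix(runif(60 * 60), 60, 60)
  fs <- frame_sequence(list(fr), 60)
  tpl <- extract_template(fs, c(20, 20, 16, 16))
  st <- solve_warp_increment(fr, tpl, c(0, 0))
  expect_equal(st$delta_u, c(0, 0))
  expect_equal(st$error, 0)
  expect_true(isSymmetric(st$hessian))

  # one-step Gauss-Newton on a smooth low-frequency texture shifted 0.3 px,
  # rendered by closed-form bilinear resampling
  set.seed(4)
  big <- scgvision:::smoothed_texture(100, 100, sigma = 4)
  f1 <- big[11:90, 11:90]
  xs <- rep(10:89 - 0.3, each = 80)  # content moved +0.3 px rightward
  ys <- rep(10:89, times = 80)
  f2 <- matrix(bilinear_sample(big, xs, ys), 80, 80)
  tpl2 <- extract_template(frame_sequence(list(f1), 60), c(20, 20, 40, 40))
  st2 <- solve_warp_increment(f2, tpl2, c(0, 0))
  expect_lt(abs(st2$delta_u[1] - 0.3), 0.05)
  expect_lt(abs(st2$delta_u[2]), 0.05)

  expect_error(solve_warp_increment(matrix(0.5, 60, 60), tpl, c(0, 0)),
               class = "scg_degenerate_texture_error")
})

test_that("tracking a static video yields an identically zero trajectory", {
  sc <- scene_from_px_waveform(rep(0, 12), seed = 5)
  tpl <- extract_template(sc$frames, sc$suggested_roi)
  tr <- track_sequence(sc$frames, tpl)
  expect_equal(tr$ux, rep(0, 12))
  expect_equal(tr$uy, rep(0, 12))
  expect_equal(tr$per_frame_error, rep(0, 12))
})

test_that("integer-shift sequences are recovered exactly", {
  offsets <- c(0, 1, 2, 3, 4)
  sc <- scene_from_px_waveform(offsets, seed = 6)
  tpl <- extract_template(sc$frames, sc$suggested_roi)
  tr <- track_sequence(sc$frames, tpl)
  expect_equal(tr$ux, offsets, tolerance = 1e-8)
  expect_equal(tr$uy, rep(0, 5), tolerance = 1e-8)
})

test_that("sub-pixel sinusoidal motion is recovered within 0.05 px RMSE", {
  t <- seq(0, 3, by = 1 / 60)
  dx <- 0.3 * sin(2 * pi * 1.2 * t)
  sc <- scene_from_px_waveform(dx, seed = 7)
  tpl <- extract_template(sc$frames, sc$suggested_roi)
  tr <- track_sequence(sc$frames, tpl)
  rmse <- sqrt(mean((tr$ux - sc$truth_displacement$x$values)^2))
  expect_lt(rmse, 0.05)
  # Gauss-Newton sanity: converged frames do not end with a larger SSD error
  # than they started with
  expect_true(all(tr$per_frame_error <= tr$initial_error + 1e-12))
})

test_that("tracking is equivariant under a constant integer translation of
           scene and ROI", {
  t <- seq(0, 1, by = 1 / 60)
  dx <- 0.4 * sin(2 * pi * 2 * t)
  sc <- scene_from_px_waveform(dx, seed = 8)
  shift <- c(5, 3)
  shifted_frames <- lapply(sc$frames$frames, function(f) {
    g <- matrix(median(f), nrow(f), ncol(f))
    g[(1 + shift[2]):nrow(f), (1 + shift[1]):ncol(f)] <-
      f[1:(nrow(f) - shift[2]), 1:(ncol(f) - shift[1])]
    g
  })
  fs2 <- frame_sequence(shifted_frames, 60)
  roi <- sc$suggested_roi
  tr1 <- track_sequence(sc$frames, extract_template(sc$frames, roi))
  tr2 <- track_sequence(fs2, extract_template(fs2, roi + c(shift, 0, 0)))
  expect_equal(tr1$ux, tr2$ux, tolerance = 1e-9)
  expect_equal(tr1$uy, tr2$uy, tolerance = 1e-9)
})

test_that("the translation Hessian equals the sum of gradient outer products", {
  set.seed(9)
  fr <- matrix(runif(50 * 50), 50, 50)
  fs <- frame_sequence(list(fr), 60)
  tpl <- extract_template(fs, c(10, 12, 16, 16))
  st <- solve_warp_increment(fr, tpl, c(0.25, -0.4))
  # general form: J = dW/du is the 2x2 identity, so H = sum (G J)^T (G J)
  # with G = (gx, gy) sampled at the warped positions
  gr <- scgvision:::frame_gradients(fr)
  xw <- as.vector(tpl$coords$x) + 0.25
  yw <- as.vector(tpl$coords$y) - 0.4
  gx <- bilinear_sample(gr$gx, xw, yw)
  gy <- bilinear_sample(gr$gy, xw, yw)
  J <- diag(2)
  H_general <- matrix(0, 2, 2)
  for (k in seq_along(gx)) {
    GJ <- matrix(c(gx[k], gy[k]), 1, 2) %*% J
    H_general <- H_general + t(GJ) %*% GJ
  }
  expect_equal(st$hessian, H_general, tolerance = 1e-10)
})

test_that("drift-corrected template updating tracks as well as the static
           template on sub-pixel motion", {
  t <- seq(0, 2, by = 1 / 60)
  dx <- 0.3 * sin(2 * pi * 1.2 * t)
  sc <- scene_from_px_waveform(dx, seed = 10)
  tpl <- extract_template(sc$frames, sc$suggested_roi)
  cfg <- tracker_config(template_update = "drift_corrected",
                        update_period_frames = 20L)
  tr <- track_sequence(sc$frames, tpl, cfg)
  rmse <- sqrt(mean((tr$ux - sc$truth_displacement$x$values)^2))
  expect_lt(rmse, 0.05)
})

test_that("a target drifting out of the frame raises a tracking-lost error
           naming the frame", {
  set.seed(11)
  big <- scgvision:::smoothed_texture(80, 80, sigma = 2)
  cut <- function(shift) {
    xs <- rep(10:69 + shift, each = 60)
    ys <- rep(10:69, times = 60)
    matrix(bilinear_sample(big, xs, ys), 60, 60)
  }
  # template hugs the left frame edge; the scene content moves left, so the
  # matched position runs off the frame
  fr <- frame_sequence(list(cut(0), cut(0), cut(2), cut(4)), 60)
  tpl <- extract_template(fr, c(0, 10, 20, 20))
  err <- tryCatch(track_sequence(fr, tpl), error = function(e) e)
  expect_s3_class(err, "scg_tracking_lost_error")
  expect_match(conditionMessage(err), "frame [34]")
})
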
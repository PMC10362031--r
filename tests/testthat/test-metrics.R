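test_that("pearson_r honors affine invariance and guards degenerate input", {
  set.seed(40)
  a <- rnorm(50)
  expect_equal(pearson_r(a, 2 * a + 3), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_error(pearson_r(rep(1, 50), a),
               class = "scg_undefined_correlation_error")
  expect_error(pearson_r(a, rnorm(49)), class = "scg_length_error")
})

test_that("DTW of a series with itself is zero along the diagonal", {
  set.seed(41)
  a <- rnorm(40)
  r <- dtw_alignment(a, a, 0.05)
  expect_equal(r$distance, 0)
  expect_equal(r$path[, 1], 1:40)
  expect_equal(r$path[, 2], 1:40)
})

test_that("DTW absorbs a repeated sample without cost when unconstrained", {
  r <- dtw_alignment(c(0, 0, 1), c(0, 1), band_fraction = 1)
  expect_equal(r$distance, 0)
})

test_that("banded DTW matches the exhaustive-path oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    m <- sample(2:12, 1)
    a <- round(rnorm(n), 2)
    b <- round(rnorm(m), 2)
    bf <- sample(c(0.05, 0.1, 0.25, 1), 1)
    got <- dtw_alignment(a, b, bf)$distance
    want <- oracle_dtw(a, b, bf)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("DTW distance is symmetric and does not increase with a wider band", {
  set.seed(43)
  for (i in 1:25) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1))
    expect_equal(dtw_alignment(a, b, 0.1)$distance,
                 dtw_alignment(b, a, 0.1)$distance, tolerance = 1e-9)
    d_narrow <- dtw_alignment(a, b, 0.05)$distance
    d_wide <- dtw_alignment(a, b, 0.2)$distance
    expect_lte(d_wide, d_narrow + 1e-12)
  }
})

test_that("DTW path obeys the step pattern and stays inside the band", {
  set.seed(44)
  a <- rnorm(30); b <- rnorm(36)
  r <- dtw_alignment(a, b, 0.1)
  p <- r$path
  expect_equal(p[1, ], c(i = 1, j = 1))
  expect_equal(p[nrow(p), ], c(i = 30, j = 36))
  steps <- diff(p)
  expect_true(all(steps[, 1] %in% 0:1 & steps[, 2] %in% 0:1))
  expect_true(all(rowSums(steps) >= 1))
  w <- ceiling(0.1 * 36)
  jstar <- 1 + (p[, 1] - 1) * 35 / 29
  istar <- 1 + (p[, 2] - 1) * 29 / 35
  expect_true(all(abs(p[, 2] - jstar) <= w + 1e-9 |
                    abs(p[, 1] - istar) <= w + 1e-9))
})

test_that("the similarity index satisfies its identity, plug-in and scaling
           contracts", {
  set.seed(45)
  g <- rnorm(60)
  self <- similarity_index(g, g)
  expect_equal(self$s, 1)
  expect_false(self$out_of_range)

  # plug-in: gold has max |.| = 2 and n_c = 4 so M = 8; the offset partner
  # yields DTW distance 0.8, hence S = (8 - 0.8) / 8 = 0.9
  gold <- c(0, 2, 0, -1)
  vis <- gold + 0.2
  expect_equal(oracle_dtw(gold, vis, 1), 0.8)  # frozen by the oracle
  sc <- similarity_index(gold, vis, band_fraction = 1)
  expect_equal(sc$m, 8)
  expect_equal(sc$d, 0.8)
  expect_equal(sc$s, 0.9)

  # joint amplitude scaling leaves S unchanged
  v2 <- g + rnorm(60, 0, 0.2)
  s1 <- similarity_index(g, v2)$s
  for (k in c(0.1, 3, 42)) {
    expect_equal(similarity_index(k * g, k * v2)$s, s1, tolerance = 1e-12)
  }

  expect_error(similarity_index(rep(0, 10), rnorm(10)),
               class = "scg_zero_normalizer_error")
})

test_that("cross-correlation lag recovers constructed delays with the stated
           sign convention", {
  set.seed(46)
  fs <- 5000
  n <- fs * 4
  base <- bandpass(uniform_signal(rnorm(n + fs), fs), 1, 30)$values
  a <- uniform_signal(base[1:n], fs)
  d <- round(0.050 * fs)
  b_del <- uniform_signal(c(rep(0, d), base[1:(n - d)]), fs)  # b trails a
  expect_equal(estimate_lag(a, b_del, 0.2), 0.050)
  expect_equal(estimate_lag(a, a, 0.2), 0)

  noisy <- uniform_signal(b_del$values + rnorm(n, 0, sqrt(10^(-1)) * sd(base)),
                          fs)
  expect_equal(estimate_lag(a, noisy, 0.2), 0.050, tolerance = 0.002)

  expect_error(estimate_lag(a, uniform_signal(rep(1, n), fs), 0.2),
               class = "scg_undefined_lag_error")
})

test_that("Bland-Altman statistics match hand computation and antisymmetry", {
  same <- bland_altman(c(60, 70, 80), c(60, 70, 80))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  off <- bland_altman(c(5, 9, 13), c(3, 7, 11))
  expect_equal(off$bias, 2)
  expect_equal(off$loa_low, 2)
  expect_equal(off$loa_high, 2)

  ba <- bland_altman(c(70, 80), c(72, 78))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 2 * sqrt(2), tolerance = 1e-9)
  expect_equal(ba$loa_high, 1.96 * 2 * sqrt(2), tolerance = 1e-9)

  set.seed(47)
  x <- rnorm(20, 70, 5); y <- rnorm(20, 70, 5)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)

  expect_error(bland_altman(1, 2), class = "scg_insufficient_pairs_error")
})
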
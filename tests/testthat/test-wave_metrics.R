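make_movie <- function(arr, dt = 1, dx = 1) cw_movie(arr, dt, dx)

test_that("box averaging equals a per-box loop", {
  set.seed(31)
  arr <- array(runif(20 * 31 * 33), c(20, 31, 33))
  m <- make_movie(arr)
  bs <- box_average(m, 15)
  expect_equal(bs$J, oracle_box_means(arr, 15))
  # uniform movie: every box trace equals the global trace
  tr <- sin(seq_len(20))
  arr2 <- array(rep(tr, 31 * 33), c(20, 31, 33))
  bs2 <- box_average(make_movie(arr2), 15)
  for (i in 1:2) for (j in 1:2)
    expect_equal(bs2$J[i, j, ], tr)
  # 2x2 blocks of constants
  blocks <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(3, 3, 4, 4), c(3, 3, 4, 4))
  arr3 <- array(rep(blocks, each = 8), c(8, 4, 4))
  arr3 <- aperm(array(blocks, c(4, 4, 8)), c(3, 1, 2))
  bs3 <- box_average(make_movie(arr3), 2)
  expect_equal(as.vector(bs3$J[, , 1]), c(1, 3, 2, 4))
  expect_error(box_average(m, 100), "frame dimensions")
})

test_that("normalize01 is an order-preserving affine map onto [0, 1]", {
  expect_equal(normalize01(c(0, 5, 10)), c(0, 0.5, 1))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(normalize01(normalize01(x)), normalize01(x))
  expect_equal(normalize01(3 * x + 7), normalize01(x))
  expect_error(normalize01(rep(2, 5)), "flat")
})

test_that("autocorrelation period matches analytic and brute-force truths", {
  t <- seq(0, 199, by = 1)
  expect_equal(period_autocorr(sin(2 * pi * t / 20), dt = 1), 20)
  # dominant component wins in a two-tone trace; brute-force oracle agrees
  x <- sin(2 * pi * t / 20) + 0.3 * sin(2 * pi * t / 7)
  r <- oracle_autocorr(x)
  # oracle scan: first local max after the first minimum
  kmin <- which.min(cumsum(diff(r) > 0) == 0)
  peaks <- which(diff(sign(diff(r))) < 0) + 1
  expect_equal(period_autocorr(x, 1), (peaks[peaks > 2][1] - 1) * 1)
  expect_equal(period_autocorr(x, 1), 20)
  # white noise reports no period
  set.seed(8)
  fp <- vapply(1:50, function(i) period_autocorr(rnorm(200), 1), 0)
  expect_true(mean(is.na(fp)) > 0.9)
  # sub-three-cycle records report no period
  expect_true(is.na(period_autocorr(sin(2 * pi * t[1:50] / 20), dt = 1)))
})

test_that("implementation matches brute-force correlation oracles to 1e-9", {
  set.seed(41)
  for (n in c(64, 257, 512)) {
    x <- rnorm(n) + sin(seq_len(n) / 5)
    r_pkg <- cortexwave:::autocorr_full(x)
    expect_lt(max(abs(r_pkg - oracle_autocorr(x))), 1e-9)
    y <- c(x[-(1:3)], rnorm(3))
    o <- oracle_xcorr(x, y, 20)
    # the package lag grid matches the oracle's correlation values
    for (l in c(-20, -3, 0, 3, 20)) {
      r_l <- o$r[o$lags == l]
      a0 <- x - mean(x); b0 <- y - mean(y)
      direct <- if (l >= 0)
        sum(a0[1:(n - l)] * b0[(1 + l):n]) / (n - l)
      else sum(b0[1:(n + l)] * a0[(1 - l):n]) / (n + l)
      expect_equal(r_l, direct, tolerance = 1e-9)
    }
  }
})

test_that("cross-correlation shift recovers known delays with sign", {
  t <- seq(0, 299, by = 1)
  a <- sin(2 * pi * t / 60) + 0.2 * sin(2 * pi * t / 13)
  b <- c(rep(a[1], 3), a[seq_len(length(a) - 3)])   # b trails a by 3 samples
  expect_equal(xcorr_shift(a, b, dt = 1), 3)
  expect_equal(xcorr_shift(a, a, dt = 1), 0)
  expect_equal(xcorr_shift(a, b, dt = 2), 6)        # seconds, not samples
  expect_error(xcorr_shift(a, rep(1, length(a)), 1), "constant")
  expect_error(xcorr_shift(a, a[-1], 1), "equal length")
})

test_that("temporal width measures FWHM on canonical peak shapes", {
  # rectangular pulses of width w on a zero baseline
  w <- 5
  x <- rep(c(rep(0, 10), rep(1, w), rep(0, 10)), 4)
  expect_equal(temporal_width(x, dt = 1), w, tolerance = 1e-6)
  # symmetric triangular peaks of base 2w -> FWHM w
  tri <- c(0:w, (w - 1):0) / w
  x2 <- rep(c(rep(0, 5), tri, rep(0, 5)), 3)
  expect_equal(temporal_width(x2, dt = 1), w, tolerance = 1e-6)
  # raised sinusoid with min 0: half-height width is half the period
  t <- seq(0, 199, by = 0.25)
  x3 <- (1 + sin(2 * pi * t / 20)) / 2
  expect_equal(temporal_width(x3, dt = 0.25), 10, tolerance = 0.25)
  expect_true(is.na(temporal_width(rep(1, 30), 1)))
})

test_that("relative amplitude follows the change-above-background formula", {
  expect_equal(relative_amplitude(rep(3, 40), dt = 1, window_s = 10), 0)
  x <- c(2, 3, 6, 4, 2, 5)
  expect_equal(relative_amplitude(x, dt = 1, window_s = 6), 2)
  # drifting baseline: windowed scan matches the brute-force oracle
  t <- seq(0, 199, by = 1)
  x2 <- 5 + 0.01 * t + sin(2 * pi * t / 25)
  expect_equal(relative_amplitude(x2, dt = 1, window_s = 25),
               oracle_window_amp(x2, 26), tolerance = 1e-12)
  expect_error(relative_amplitude(c(-1, 2, 3, 4, 5, 6, 7, 8), 1, 4),
               "positive")
})

test_that("kymographs reslice along a 1-px line with wave geometry intact", {
  pw <- plane_wave_movie(period = 24, wavelength = 16, nx = 48, ny = 16,
                         dt = 2, duration = 240, dx = 1)
  ky <- kymograph(pw$movie, line = 8, axis = "row")
  expect_equal(dim(ky), c(120, 48))
  # stripe slope = wave speed: the peak position advances by speed*dt/dx px
  # per frame; track the crest with phase-aware circular mean
  crest <- apply(ky[1:60, ], 1, which.max)
  d_crest <- diff(crest) %% 16
  speed_px <- mean(d_crest) / 2              # px per s (dt = 2)
  expect_equal(speed_px, pw$truth$speed_um_s, tolerance = 0.1)
  # orthogonal line: horizontal bands with the temporal period
  ky2 <- kymograph(pw$movie, line = 24, axis = "col")
  expect_equal(period_autocorr(ky2[, 5], dt = 2), 24)
  expect_equal(ky2[1, ], rep(ky2[1, 1], 16))   # bands: uniform across y
  # static movie: all kymograph rows identical
  arr <- aperm(array(matrix(runif(16 * 48), 16, 48), c(16, 48, 10)),
               c(3, 1, 2))
  ky3 <- kymograph(cw_movie(arr, 2, 1), line = 4, axis = "row")
  expect_true(all(apply(ky3, 2, function(cc) all(cc == cc[1]))))
  expect_error(kymograph(pw$movie, 99, "row"), "bounds")
})

test_that("summarize recovers generator ground truth per box", {
  pw <- plane_wave_movie(period = 24, wavelength = 20, baseline = 1,
                         amplitude = 1, nx = 60, ny = 60, dx = 0.267,
                         dt = 2, duration = 360)
  sm <- summarize(pw$movie, box_px = 5)
  s <- sm$summary
  expect_lt(abs(s$period_s["mean"] - 24), 2)
  expect_lt(abs(s$width_s["mean"] - pw$truth$fwhm_s), 2)
  expect_lt(abs(s$rel_amplitude["mean"] - pw$truth$rel_amplitude) /
              pw$truth$rel_amplitude, 0.05)
  # uniform oscillating movie: per-box period identical to the global one
  t <- seq_len(64)
  arr <- array(rep(2 + sin(2 * pi * t / 16), 30 * 30), c(64, 30, 30))
  smu <- summarize(cw_movie(arr, 1, 1), box_px = 15)
  expect_true(all(smu$per_box$period_s == 16))
  expect_error(summarize(pw$movie,
                         cw_movie(array(1 + sin(seq_len(8)) %o% matrix(1, 4, 4),
                                        c(8, 4, 4)), 1, 1)),
               "shape mismatch")
})

test_that("metrics are invariant under affine intensity maps", {
  pw <- plane_wave_movie(period = 30, wavelength = 18, nx = 40, ny = 40,
                         dx = 0.5, dt = 2, duration = 300, noise_sd = 0.02)
  m1 <- pw$movie
  m2 <- cw_movie(2.5 * m1$data + 40, m1$dt, m1$dx)
  s1 <- summarize(m1, box_px = 5)
  s2 <- summarize(m2, box_px = 5)
  expect_equal(s1$summary$period_s, s2$summary$period_s)
  expect_equal(s1$summary$width_s, s2$summary$width_s, tolerance = 1e-8)
  # pure scaling preserves the amplitude ratio
  m3 <- cw_movie(2.5 * m1$data, m1$dt, m1$dx)
  s3 <- summarize(m3, box_px = 5)
  expect_equal(s1$summary$rel_amplitude, s3$summary$rel_amplitude,
               tolerance = 1e-8)
})

test_that("halving dt does not worsen period or shift recovery", {
  for (dt in c(2, 1)) {
    pw <- plane_wave_movie(period = 23, wavelength = 20, nx = 30, ny = 30,
                           dx = 0.5, dt = dt, duration = 300)
    per <- period_autocorr(box_average(pw$movie, 5)$J[3, 3, ], dt)
    expect_lte(abs(per - 23), dt)
  }
})
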
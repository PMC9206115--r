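test_that("correlated noise fields have exact sample moments", {
  g <- cw_grid(64, 64, dx = 1)
  set.seed(5)
  W0 <- make_noise_field(g, 0, s = 4)
  expect_true(all(W0 == 1))
  W <- make_noise_field(g, 0.3, s = 4)
  expect_equal(mean(W), 1, tolerance = 1e-12)
  n <- length(W)
  expect_equal(sqrt(sum((W - 1)^2) / n), 0.3, tolerance = 1e-12)
  # sub-lattice correlation length carries a warning attribute
  Wws <- make_noise_field(g, 0.3, s = 0.5)
  expect_match(attr(Wws, "warning"), "correlation")
  expect_error(make_noise_field(g, -1, 2), "non-negative")
})

test_that("noise autocorrelation e-folds at twice the kernel sd", {
  g <- cw_grid(128, 128, dx = 1)
  s <- 4
  set.seed(9)
  # radial autocorrelation pooled over realizations (FFT-free oracle:
  # direct shifted products along the axes)
  corr_at <- function(W, r) {
    z <- W - mean(W)
    sh_x <- z[, c((r + 1):ncol(z), 1:r)]
    sh_y <- z[c((r + 1):nrow(z), 1:r), ]
    (sum(z * sh_x) + sum(z * sh_y)) / (2 * sum(z^2))
  }
  rs <- 1:12
  acc <- numeric(length(rs))
  for (k in 1:40) {
    W <- make_noise_field(g, 0.3, s)
    acc <- acc + vapply(rs, function(r) corr_at(W, r), 0)
  }
  acc <- acc / 40
  # e-folding distance: first crossing of 1/e, linearly interpolated
  i <- which(acc < exp(-1))[1]
  r_efold <- rs[i - 1] + (acc[i - 1] - exp(-1)) / (acc[i - 1] - acc[i])
  expect_equal(r_efold, 2 * s, tolerance = 0.1)
})

test_that("the periodic Laplacian is exact on lattice eigenmodes", {
  n <- 32; dx <- 0.7
  expect_equal(laplacian(matrix(3.2, n, n), dx), matrix(0, n, n))
  for (m in c(1, 5, 13)) {
    f <- matrix(cos(2 * pi * m * (seq_len(n) - 1) / n), n, n, byrow = TRUE)
    ev <- -(4 / dx^2) * sin(pi * m / n)^2
    expect_equal(laplacian(f, dx), ev * f, tolerance = 1e-10)
  }
  set.seed(2)
  r <- matrix(rnorm(n * n), n)
  expect_lt(abs(sum(laplacian(r, dx))), 1e-9 * sum(abs(r)))
})

test_that("step is the definitional Euler update with a floor", {
  p <- cw_params(); p$beta <- 0.75
  row <- pick_canonical(uniform_steady_state(p))
  st <- cw_state(matrix(row$RT_ss, 16, 16), matrix(row$RD_ss, 16, 16),
                 matrix(row$F_ss, 16, 16), dx = 1)
  out <- step(st, 1, p, dt = 0.01)
  expect_equal(out$RT, st$RT, tolerance = 1e-12)
  # single step equals state + dt * rhs before flooring
  set.seed(4)
  st2 <- cw_state(matrix(runif(256, 0.5, 2), 16),
                  matrix(runif(256, 0.5, 2), 16),
                  matrix(runif(256, 0.5, 2), 16), dx = 1)
  d <- rhs_reduced(st2, 1, p)
  out2 <- step(st2, 1, p, dt = 0.01)
  expect_equal(out2$RT, st2$RT + 0.01 * d$dRT)
  expect_equal(out2$F, st2$F + 0.01 * d$dF)
  expect_error(step(st2, 1, p, dt = 10), "stability bound")
})

test_that("the integrator converges at first order", {
  p <- cw_params(); p$beta <- 0.75
  g <- cw_grid(16, 16, dx = 1)
  row <- pick_canonical(uniform_steady_state(p))
  mk <- function(v) matrix(v, 16, 16)
  pert <- mk(row$RT_ss) * (1 + 0.1 * sin(2 * pi * seq_len(16) / 16))
  init <- cw_state(pert, mk(row$RD_ss), mk(row$F_ss), dx = 1)
  endf <- function(dt) {
    tr <- simulate(p, g, duration = 4, dt = dt, sample_every = 4, seed = 1,
                   init = init, sigma_override = 0)
    tr$frames[[length(tr$frames)]]$RT
  }
  # fine steps keep the O(dt^2) remainder out of the Richardson ratio
  ref <- endf(0.0003125)
  e1 <- max(abs(endf(0.005) - ref))
  e2 <- max(abs(endf(0.0025) - ref))
  slope <- log2(e1 / e2)
  expect_equal(slope, 1, tolerance = 0.1)
})

test_that("simulation preserves the uniform manifold and is bit-reproducible", {
  p <- cw_params(); p$beta <- 0.75
  g <- cw_grid(32, 32, dx = 1)
  tr <- simulate(p, g, duration = 40, dt = 0.02, sample_every = 10,
                 seed = 1, init = "steady", sigma_override = 0)
  row <- pick_canonical(uniform_steady_state(p))
  dev <- vapply(tr$frames, function(f)
    max(abs(f$RT - row$RT_ss), abs(f$F - row$F_ss)), 0)
  expect_lt(max(dev), 1e-10)
  # determinism with noise on
  t1 <- simulate(p, g, duration = 30, dt = 0.02, sample_every = 10, seed = 7)
  t2 <- simulate(p, g, duration = 30, dt = 0.02, sample_every = 10, seed = 7)
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate(p, g, duration = 30, dt = 0.02, sample_every = 10, seed = 8)
  expect_false(identical(t3$frames, t1$frames))
})

test_that("full-model integration conserves total Rho", {
  fp <- cw_full_params(k5_star = 1, RD0 = 0.5, eta = 1e-3, beta = 0.3)
  g <- cw_grid(12, 12, dx = 1.5)
  rp <- reduce_full_params(fp)
  row <- pick_canonical(uniform_steady_state(rp))
  mk <- function(v) matrix(v, 12, 12)
  pert <- mk(row$RT_ss) * (1 + 0.1 * cos(2 * pi * seq_len(12) / 12))
  st <- cw_state(pert, mk(row$RD_ss), mk(row$F_ss), RDc = mk(fp$RD0),
                 dx = 1.5)
  tr <- simulate_full(fp, g, duration = 40, dt = 0.02, sample_every = 5,
                      init = st)
  tot <- vapply(tr$frames, function(f)
    sum(f$RT + f$RD + f$RDc / fp$eta), 0)
  tot0 <- sum(st$RT + st$RD + st$RDc / fp$eta)
  expect_lt(max(abs(tot - tot0)) / tot0, 1e-10)
})

test_that("noise perturbs stable-state averages only at the Jensen O(sigma^2) scale", {
  # multiplicative disassembly noise makes E[F] exceed F_ss by ~sigma^2
  # (E[1/W] > 1/E[W]); the ensemble mean must sit within that bound and
  # the bias must shrink with sigma.
  p <- cw_params(); p$beta <- 0.3; p$f <- 5
  g <- cw_grid(12, 12, dx = 2)
  row <- pick_canonical(uniform_steady_state(p))
  bias_at <- function(sig) {
    means <- vapply(1:100, function(sd_) {
      tr <- simulate(p, g, duration = 40, dt = 0.05, sample_every = 40,
                     seed = sd_, init = "steady", sigma_override = sig)
      mean(tr$frames[[length(tr$frames)]]$F)
    }, 0)
    c(bias = mean(means) - row$F_ss, sem = sd(means) / sqrt(length(means)))
  }
  b1 <- bias_at(0.1)
  expect_lt(abs(b1["bias"]), 0.1^2 * row$F_ss + 3 * b1["sem"])
  b2 <- bias_at(0.05)
  expect_lt(abs(b2["bias"]), abs(b1["bias"]))
})
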
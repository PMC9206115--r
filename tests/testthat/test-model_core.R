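test_that("reaction_rate matches its stated functional form", {
  p <- cw_params(k0 = 0.1)
  # all RT-proportional terms vanish at rt = 0, leaving k0 * rd
  expect_equal(reaction_rate(0, 1, 17, p), 0.1)
  expect_equal(reaction_rate(0, 0, 5, p), 0)
  # hand evaluation with unit constants: (0.1 + 0.5)*1 - (1 + 2)*1 = -2.4
  p1 <- cw_params(k0 = 0.1, k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1,
                  k7 = 1, k8 = 1, k9 = 1, k10 = 1, alpha = 1, beta = 1,
                  D_RT = 1, D_RD = 1, D_F = 1)
  expect_equal(reaction_rate(1, 1, 1, p1), -2.4)
  expect_error(reaction_rate(-0.1, 1, 1, p), "non-negative")
})

test_that("actin_rate matches its stated functional form", {
  p <- cw_params(k7 = 0.1, k8 = 1, k9 = 1, k10 = 0.5)
  expect_equal(actin_rate(0, 0, 1, p), 0.1)
  expect_equal(actin_rate(0, p$k7 / p$k10, 1, p), 0)
  expect_equal(actin_rate(1, 2, 1, p), 0.1 + 0.5 - 1.0)
  expect_error(actin_rate(1, -1, 1, p), "non-negative")
  expect_error(actin_rate(1, 1, NaN, p), "finite")
})

test_that("kinetics are monotone in the feedback directions", {
  set.seed(42)
  for (rep in 1:10) {
    p <- random_params()
    rt <- runif(1, 0.1, 3); rd <- runif(1, 0.1, 3)
    fs <- sort(runif(5, 0, 10))
    rr <- vapply(fs, function(f) reaction_rate(rt, rd, f, p), 0)
    expect_true(all(diff(rr) < 0))   # F-actin inhibits active Rho
    rds <- sort(runif(5, 0, 5))
    rr2 <- vapply(rds, function(r) reaction_rate(rt, r, 1, p), 0)
    expect_true(all(diff(rr2) > 0))  # substrate promotes activation
  }
})

test_that("rhs_reduced decouples to pointwise kinetics and matches a brute-force oracle", {
  p <- cw_params()
  p$beta <- 0.8
  # D = 0: derivative equals the pointwise reaction terms
  p0 <- p; p0$D_RT <- 0; p0$D_RD <- 0; p0$D_F <- 0
  set.seed(1)
  st <- cw_state(matrix(runif(64, 0.1, 2), 8), matrix(runif(64, 0.1, 2), 8),
                 matrix(runif(64, 0.1, 2), 8), dx = 0.5)
  d <- rhs_reduced(st, 1, p0)
  R <- reaction_rate(st$RT, st$RD, st$F, p0)
  expect_equal(d$dRT, R)
  expect_equal(d$dRD, p0$k5 - p0$k6 * st$RD - R)
  expect_equal(d$dF, actin_rate(st$RT, st$F, 1, p0))

  # random smooth state on 32x32: term-by-term loop oracle
  n <- 32
  xs <- outer(seq_len(n), seq_len(n), function(i, j)
    1 + 0.3 * sin(2 * pi * i / n) * cos(4 * pi * j / n))
  st2 <- cw_state(xs, 1.3 * xs, 0.7 * xs, dx = 0.8)
  W <- matrix(1 + 0.1 * sin(2 * pi * seq_len(n) / n), n, n)
  d2 <- rhs_reduced(st2, W, p)
  lap_loop <- function(f) {
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      iu <- if (i == 1) n else i - 1; id <- if (i == n) 1 else i + 1
      jl <- if (j == 1) n else j - 1; jr <- if (j == n) 1 else j + 1
      out[i, j] <- (f[iu, j] + f[id, j] + f[i, jl] + f[i, jr] -
                      4 * f[i, j]) / 0.8^2
    }
    out
  }
  ref_rt <- matrix(0, n, n); ref_rd <- matrix(0, n, n); ref_f <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    v <- oracle_rhs_uniform(c(st2$RT[i, j], st2$RD[i, j], st2$F[i, j]), p,
                            w = W[i, j])
    ref_rt[i, j] <- v[1]; ref_rd[i, j] <- v[2]; ref_f[i, j] <- v[3]
  }
  expect_equal(d2$dRT, ref_rt + p$D_RT * lap_loop(st2$RT), tolerance = 1e-12)
  expect_equal(d2$dRD, ref_rd + p$D_RD * lap_loop(st2$RD), tolerance = 1e-12)
  expect_equal(d2$dF, ref_f + p$D_F * lap_loop(st2$F), tolerance = 1e-12)

  expect_error(rhs_reduced(st2, matrix(1, 4, 4), p), "shape")
})

test_that("rhs_full balances exchange and conserves total Rho", {
  fp <- cw_full_params(k5_star = 2, RD0 = 0.25, eta = 1e-3)
  # exchange balance: k5_star * RDc = k6 * RD and R = 0 pointwise
  rd <- 0.4; rdc <- fp$k6 * rd / fp$k5_star
  st <- cw_state(matrix(0, 8, 8), matrix(rd, 8, 8), matrix(0, 8, 8),
                 RDc = matrix(rdc, 8, 8), dx = 1)
  fp0 <- fp; fp0$k0 <- 0   # kills the reaction at RT = 0
  d <- rhs_full(st, 1, fp0)
  expect_equal(max(abs(d$dRD)), 0)
  expect_equal(max(abs(d$dRDc)), 0)
  # sum rule on a periodic grid including diffusion
  set.seed(3)
  st2 <- cw_state(matrix(runif(64, 0.1, 1), 8), matrix(runif(64, 0.1, 1), 8),
                  matrix(runif(64, 0.1, 1), 8),
                  RDc = matrix(runif(64, 0.1, 1), 8), dx = 0.7)
  d2 <- rhs_full(st2, 1, fp)
  tot <- sum(d2$dRT + d2$dRD + d2$dRDc / fp$eta)
  expect_lt(abs(tot), 1e-9 * sum(abs(st2$RT)))
  expect_error(rhs_full(st2, 1, `$<-`(fp, "eta", 0)), "rhs_reduced")
})

test_that("full model converges to the reduced model as eta -> 0", {
  fp <- cw_full_params(k5_star = 1, RD0 = 0.5, beta = 0.3)
  rp <- reduce_full_params(fp)
  expect_equal(rp$k5, fp$k5_star * fp$RD0)
  expect_equal(reduce_full_params(cw_full_params(k5_star = 2, RD0 = 3))$k5, 6)
  expect_equal(reduce_full_params(cw_full_params(k5_star = 2, RD0 = 0))$k5, 0)

  g <- cw_grid(8, 8, dx = 2)
  ssr <- uniform_steady_state(rp)
  row <- ssr[ssr$canonical, ]
  mk <- function(v) matrix(v, 8, 8)
  pert <- mk(row$RT_ss) * (1 + 0.05 * sin(2 * pi * seq_len(8) / 8))
  # reduced reference via the package integrator
  st0 <- cw_state(pert, mk(row$RD_ss), mk(row$F_ss), dx = 2)
  ref <- simulate(rp, g, duration = 100, dt = 0.01, sample_every = 100,
                  seed = 1, init = st0, sigma_override = 0)
  end_ref <- ref$frames[[length(ref$frames)]]
  errs <- vapply(c(1e-3, 1e-4, 1e-5), function(eta) {
    fpe <- fp; fpe$eta <- eta
    st <- cw_state(pert, mk(row$RD_ss), mk(row$F_ss), RDc = mk(fp$RD0),
                   dx = 2)
    tr <- simulate_full(fpe, g, duration = 100, dt = 0.01,
                        sample_every = 100, init = st)
    endf <- tr$frames[[length(tr$frames)]]
    max(abs(endf$RT - end_ref$RT) / max(end_ref$RT),
        abs(endf$F - end_ref$F) / max(end_ref$F))
  }, 0)
  expect_true(all(diff(errs) < 0))          # monotone in eta
  expect_lt(errs[3], 1e-3)                  # eta = 1e-5 is reduced in practice
})

test_that("uniform_steady_state finds exact roots and the canonical branch", {
  # closed-form root with no basal activation
  p <- cw_params(k0 = 0)
  ss <- uniform_steady_state(p)
  z <- ss[which.min(ss$RT_ss), ]
  expect_equal(z$RT_ss, 0)
  expect_equal(z$RD_ss, p$k5 / p$k6)
  expect_equal(z$F_ss, p$k7 / p$k10)
  # residual contract on random valid sets
  set.seed(7)
  for (rep in 1:20) {
    pr <- random_params()
    ssr <- uniform_steady_state(pr)
    expect_true(all(ssr$residual < 1e-10))
    expect_true(all(ssr$RT_ss >= 0 & ssr$F_ss >= 0))
    expect_equal(sum(ssr$canonical), 1)
  }
  # zone ordering: active Rho and F-actin higher at weak negative feedback
  p1 <- cw_params(); p1$beta <- 0.3
  p2 <- cw_params(); p2$beta <- 3
  r1 <- pick_canonical(uniform_steady_state(p1))
  r2 <- pick_canonical(uniform_steady_state(p2))
  expect_gt(r1$RT_ss, r2$RT_ss)
  expect_gt(r1$F_ss, r2$F_ss)
  # canonical root agrees with an independent RK4 relaxation oracle
  pm <- cw_params(); pm$beta <- 1.6   # inside the multistable fold
  ssm <- uniform_steady_state(pm)
  xr <- oracle_relax(pm)
  expect_equal(pick_canonical(ssm)$RT_ss, xr[1], tolerance = 1e-4)
})

test_that("fixed points are genuine zeros of the spatial model", {
  set.seed(11)
  for (rep in 1:5) {
    p <- random_params()
    row <- pick_canonical(uniform_steady_state(p))
    st <- cw_state(matrix(row$RT_ss, 8, 8), matrix(row$RD_ss, 8, 8),
                   matrix(row$F_ss, 8, 8), dx = 1)
    d <- rhs_reduced(st, 1, p)
    expect_lt(max(abs(d$dRT), abs(d$dRD), abs(d$dF)), 1e-10)
  }
})

test_that("parameter validation enforces the physical constraints", {
  expect_error(cw_params(k3 = -1), "non-negative")
  expect_error(cw_params(D_RT = 2, D_RD = 1), "D_RT")
  expect_error(cw_params(s = 0), "positive")
  expect_error(cw_params(f = -1), "positive")
  expect_silent(cw_params(alpha = 0))
})
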
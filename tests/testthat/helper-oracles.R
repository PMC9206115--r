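# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

oracle_autocorr <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  r <- numeric(n)
  for (l in 0:(n - 1)) {
    acc <- 0
    for (t in 1:(n - l)) acc <- acc + x[t] * x[t + l]
    r[l + 1] <- acc
  }
  r / r[1]
}

oracle_xcorr <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  lags <- (-max_lag):max_lag
  r <- numeric(length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]; acc <- 0; cnt <- 0
    for (t in 1:n) {
      u <- t + l
      if (u >= 1 && u <= n) { acc <- acc + a[t] * b[u]; cnt <- cnt + 1 }
    }
    r[i] <- acc / cnt
  }
  list(lags = lags, r = r)
}

oracle_box_means <- function(arr, box) {
  d <- dim(arr)
  ni <- d[2] %/% box; nj <- d[3] %/% box
  J <- array(NA_real_, c(ni, nj, d[1]))
  for (i in seq_len(ni)) for (j in seq_len(nj)) for (k in seq_len(d[1])) {
    acc <- 0
    for (a in 1:box) for (b in 1:box)
      acc <- acc + arr[k, (i - 1) * box + a, (j - 1) * box + b]
    J[i, j, k] <- acc / box^2
  }
  J
}

# uniform reaction RHS, written straight from the kinetic scheme
oracle_rhs_uniform <- function(x, p, w = 1) {
  rt <- x[1]; rd <- x[2]; f <- x[3]
  act <- p$k0 + p$alpha * p$k1 * rt^3 / (1 + p$k2 * rt^2)
  inact <- p$k3 + p$k4 * (1 + p$beta) * f
  R <- act * rd - inact * rt
  c(R, p$k5 - p$k6 * rd - R,
    p$k7 + p$k8 * rt^2 / (1 + p$k9 * rt^2) - p$k10 * w * f)
}

# RK4 relaxation oracle (independent of the package integrator)
oracle_relax <- function(p, x0 = c(1e-3, p$k5 / p$k6, p$k7 / p$k10),
                         tmax = 3000, dt = 0.05) {
  x <- x0
  for (i in seq_len(ceiling(tmax / dt))) {
    a <- oracle_rhs_uniform(x, p)
    b <- oracle_rhs_uniform(pmax(x + dt / 2 * a, 0), p)
    cc <- oracle_rhs_uniform(pmax(x + dt / 2 * b, 0), p)
    d <- oracle_rhs_uniform(pmax(x + dt * cc, 0), p)
    x <- pmax(x + dt / 6 * (a + 2 * b + 2 * cc + d), 0)
  }
  x
}

oracle_jacobian_fd <- function(p, ss_row, h = 1e-6) {
  x0 <- c(ss_row$RT_ss, ss_row$RD_ss, ss_row$F_ss)
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J[, j] <- (oracle_rhs_uniform(x0 + e, p) -
               oracle_rhs_uniform(x0 - e, p)) / (2 * h)
  }
  J
}

# exhaustive plaquette winding sum over a wrapped phase field
oracle_total_winding <- function(theta, periodic = TRUE) {
  wr <- function(d) { y <- (d + pi) %% (2 * pi) - pi; if (y <= -pi) pi else y }
  ny <- nrow(theta); nx <- ncol(theta)
  imax <- if (periodic) ny else ny - 1
  jmax <- if (periodic) nx else nx - 1
  tot <- 0
  for (i in 1:imax) for (j in 1:jmax) {
    i2 <- if (i == ny) 1 else i + 1
    j2 <- if (j == nx) 1 else j + 1
    s <- wr(theta[i, j2] - theta[i, j]) + wr(theta[i2, j2] - theta[i, j2]) +
      wr(theta[i2, j] - theta[i2, j2]) + wr(theta[i, j] - theta[i2, j])
    tot <- tot + round(s / (2 * pi))
  }
  tot
}

oracle_window_amp <- function(x, w) {
  n <- length(x)
  exc <- numeric(n - w + 1)
  for (i in seq_len(n - w + 1)) {
    lo <- Inf; hi <- -Inf
    for (t in i:(i + w - 1)) { lo <- min(lo, x[t]); hi <- max(hi, x[t]) }
    exc[i] <- hi - lo
  }
  mean(exc) / min(x)
}

# random valid parameter set in a band around the calibrated defaults;
# rejection-sampled so a non-negative uniform steady state exists
random_params <- function(span = c(0.5, 2)) {
  repeat {
    d <- cw_params()
    for (nm in c("k0", "k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8",
                 "k9", "k10"))
      d[[nm]] <- d[[nm]] * exp(stats::runif(1, log(span[1]), log(span[2])))
    d$beta <- stats::runif(1, 0, 5)
    ok <- tryCatch({ uniform_steady_state(d); TRUE },
                   error = function(e) FALSE)
    if (ok) return(d)
  }
}
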
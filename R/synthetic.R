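#' Periodic pulse profile with analytic FWHM
#'
#' Raised-cosine profile on the wrapped phase `u` in `(-pi, pi]`: active
#' where `|u| <= pi * duty`, with `g = (1 + cos(u/duty))/2` there and 0
#' elsewhere.  `duty = 1` is the pure raised cosine.  The full width at
#' half maximum is `duty/2` of a cycle, so a temporal period `T` gives
#' peaks of FWHM `duty * T / 2` -- the generator's analytic width truth.
#'
#' @param u phase (radians, any range; wrapped internally).
#' @param duty active fraction of the cycle in (0, 1].
#' @return Profile values in `[0, 1]`.
#' @export
pulse_profile <- function(u, duty = 1) {
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  u <- wrap_phase(u)
  g <- ifelse(abs(u) <= pi * duty, (1 + cos(u / duty)) / 2, 0)
  g
}

#' Synthetic plane-wave movie with ground truth
#'
#' Intensity `baseline + amplitude * g(k.x - w t)` with the raised-cosine
#' profile of [pulse_profile()], plus optional additive Gaussian noise.
#' Emulates lamellar wave trains of thick, gently curved cortical waves.
#'
#' @param period temporal period (s).
#' @param wavelength spatial wavelength (um); must exceed `2 * dx`.
#' @param baseline,amplitude intensity baseline (> 0) and excursion.
#' @param angle propagation direction (rad; 0 = along +x).
#' @param nx,ny frame size (px).
#' @param dx pixel size (um); default mirrors the classic imaging scale
#'   0.267 um/px (15 px is about 4 um).
#' @param dt frame interval (s).
#' @param duration movie length (s).
#' @param noise_sd additive Gaussian noise sd.
#' @param duty pulse duty cycle (1 = sinusoidal-looking raised cosine).
#' @param seed RNG seed for the noise.
#' @return List with `movie` (a [cw_movie()]) and `truth` (named list:
#'   `period_s`, `wavelength_um`, `speed_um_s`, `rel_amplitude`, `fwhm_s`,
#'   `generator`, `seed`).
#' @export
plane_wave_movie <- function(period = 24, wavelength = 20, baseline = 1,
                             amplitude = 1, angle = 0, nx = 64, ny = 64,
                             dx = 0.267, dt = 4, duration = 240,
                             noise_sd = 0, duty = 1, seed = 1) {
  if (period <= 0 || wavelength <= 0) stop("period and wavelength must be positive")
  if (baseline <= 0) stop("baseline must be positive")
  if (wavelength < 2 * dx)
    stop("wavelength below the lattice Nyquist limit 2*dx (aliasing)")
  nt <- max(8L, round(duration / dt))
  k <- 2 * pi / wavelength
  w <- 2 * pi / period
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  sp <- k * (cos(angle) * matrix(xs, ny, nx, byrow = TRUE) +
             sin(angle) * matrix(ys, ny, nx))
  set.seed(seed)
  arr <- array(0, c(nt, ny, nx))
  for (tindex in seq_len(nt)) {
    u <- sp - w * (tindex - 1) * dt
    arr[tindex, , ] <- baseline + amplitude * pulse_profile(u, duty)
  }
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  truth <- list(period_s = period, wavelength_um = wavelength,
                speed_um_s = wavelength / period,
                rel_amplitude = amplitude / baseline,
                fwhm_s = duty * period / 2,
                generator = "plane_wave", seed = seed)
  list(movie = cw_movie(arr, dt, dx, "synthetic_plane_wave"), truth = truth)
}

#' Synthetic spiral-wave movie with ground truth
#'
#' Intensity follows `cos(w t + chirality * arms * psi - k r)` mapped
#' through the raised-cosine profile, where `psi` is the polar angle about
#' the core; the reconstructed oscillation phase then carries a defect of
#' charge `chirality * arms` at the core.  Emulates involute single- and
#' two-armed spirals.
#'
#' @param arms 1 or 2 spiral arms.
#' @param chirality +1 or -1.
#' @param period,wavelength,baseline,amplitude,nx,ny,dx,dt,duration,duty,seed
#'   as in [plane_wave_movie()].
#' @param noise_sd additive Gaussian noise sd.
#' @return List with `movie` and `truth` (adds `core_x`, `core_y` in px and
#'   `charge`).
#' @export
spiral_movie <- function(arms = 1, chirality = 1, period = 24,
                         wavelength = 20, baseline = 1, amplitude = 1,
                         nx = 64, ny = 64, dx = 0.267, dt = 4,
                         duration = 240, noise_sd = 0, duty = 1, seed = 1) {
  if (!arms %in% c(1, 2)) stop("arms must be 1 or 2")
  if (!chirality %in% c(-1, 1)) stop("chirality must be +1 or -1")
  if (wavelength < 2 * dx) stop("wavelength below 2*dx (aliasing)")
  nt <- max(8L, round(duration / dt))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  Y <- matrix(seq_len(ny), ny, nx) - cy
  psi <- atan2(Y, X)
  r <- sqrt(X^2 + Y^2) * dx
  k <- 2 * pi / wavelength
  w <- 2 * pi / period
  set.seed(seed)
  arr <- array(0, c(nt, ny, nx))
  for (tindex in seq_len(nt)) {
    u <- w * (tindex - 1) * dt + chirality * arms * psi - k * r
    arr[tindex, , ] <- baseline + amplitude * pulse_profile(u, duty)
  }
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  truth <- list(period_s = period, wavelength_um = wavelength,
                speed_um_s = wavelength / period,
                rel_amplitude = amplitude / baseline,
                fwhm_s = duty * period / 2, core_x = cx, core_y = cy,
                charge = chirality * arms, generator = "spiral", seed = seed)
  list(movie = cw_movie(arr, dt, dx, "synthetic_spiral"), truth = truth)
}

#' Lagged follower channel for a base movie
#'
#' Per-pixel delayed (linear interpolation in time, edge-clamped), causally
#' smoothed (single-pole exponential filter) and rescaled copy of a base
#' movie -- a stand-in for a trailing reporter.  Useful preset lags from
#' cross-correlation measurements in cortical-wave movies: 15.7 s and 18 s
#' (GAP recruitment after Rho activation) and 57 s (myosin after Rho).
#'
#' @param base a [cw_movie()].
#' @param lag delay (s), non-negative and below the movie duration.
#' @param smoothing exponential time constant (s); 0 disables smoothing.
#' @param gain multiplicative intensity rescaling.
#' @return List with `movie` and `truth` (`lag_s`, `smoothing_s`, `gain`).
#' @export
follower_movie <- function(base, lag = 18, smoothing = 0, gain = 1) {
  stopifnot(inherits(base, "cw_movie"))
  if (lag < 0) stop("lag must be non-negative")
  nt <- dim(base$data)[1]
  if (lag >= nt * base$dt) stop("lag must be below the movie duration")
  shift <- lag / base$dt
  lo <- floor(shift); frac <- shift - lo
  idx <- pmax(seq_len(nt) - lo, 1)
  idx2 <- pmax(idx - 1, 1)
  out <- (1 - frac) * base$data[idx, , , drop = FALSE] +
    frac * base$data[idx2, , , drop = FALSE]
  if (smoothing > 0) {
    a <- exp(-base$dt / smoothing)
    for (tindex in 2:nt)
      out[tindex, , ] <- a * out[tindex - 1, , ] + (1 - a) * out[tindex, , ]
  }
  out <- gain * out
  truth <- list(lag_s = lag, smoothing_s = smoothing, gain = gain,
                generator = "follower")
  list(movie = cw_movie(out, base$dt, base$dx,
                        paste0(base$channel, "_follower")), truth = truth)
}

#' Synthetic movie of stochastic activity pulses (flickers)
#'
#' Poisson-seeded Gaussian space-time bumps on a constant baseline,
#' optionally drifting a short distance (pulse-mediated propagation);
#' emulates non-propagating flickers and short-run pulses.
#'
#' @param rate event rate (events / s / um^2).
#' @param pulse_fwhm_s temporal FWHM of each pulse (s).
#' @param pulse_radius_um spatial Gaussian sigma of each pulse (um).
#' @param propagation `"none"` (static flickers) or `"short-run"` (each
#'   pulse drifts with a random velocity of magnitude `drift_um_s`).
#' @param drift_um_s drift speed for `"short-run"` pulses.
#' @param baseline constant background intensity (> 0).
#' @param amplitude peak amplitude of one pulse.
#' @param nx,ny,dx,dt,duration,seed as in [plane_wave_movie()].
#' @return List with `movie` and `truth` (`events` data frame with `t0`,
#'   `x0`, `y0` in px, plus the generator settings and the expected count).
#' @export
pulse_movie <- function(rate = 2e-4, pulse_fwhm_s = 12, pulse_radius_um = 2,
                        propagation = c("none", "short-run"),
                        drift_um_s = 0.5, baseline = 0.2, amplitude = 1,
                        nx = 64, ny = 64, dx = 0.267, dt = 4,
                        duration = 240, seed = 1) {
  propagation <- match.arg(propagation)
  if (rate <= 0) stop("rate must be positive")
  nt <- max(8L, round(duration / dt))
  area <- nx * ny * dx^2
  set.seed(seed)
  n_ev <- stats::rpois(1, rate * area * duration)
  ev <- data.frame(t0 = stats::runif(n_ev, 0, duration),
                   x0 = stats::runif(n_ev, 1, nx),
                   y0 = stats::runif(n_ev, 1, ny),
                   vx = numeric(n_ev), vy = numeric(n_ev))
  if (propagation == "short-run" && n_ev > 0) {
    th <- stats::runif(n_ev, 0, 2 * pi)
    ev$vx <- drift_um_s * cos(th) / dx    # px/s
    ev$vy <- drift_um_s * sin(th) / dx
  }
  sig_t <- pulse_fwhm_s / (2 * sqrt(2 * log(2)))
  sig_px <- pulse_radius_um / dx
  arr <- array(baseline, c(nt, ny, nx))
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny), ny, nx)
  ts <- (seq_len(nt) - 1) * dt
  for (e in seq_len(n_ev)) {
    tw <- which(abs(ts - ev$t0[e]) < 4 * sig_t)
    for (tindex in tw) {
      tdiff <- ts[tindex] - ev$t0[e]
      cxp <- ev$x0[e] + ev$vx[e] * tdiff
      cyp <- ev$y0[e] + ev$vy[e] * tdiff
      amp <- amplitude * exp(-tdiff^2 / (2 * sig_t^2))
      arr[tindex, , ] <- arr[tindex, , ] +
        amp * exp(-((X - cxp)^2 + (Y - cyp)^2) / (2 * sig_px^2))
    }
  }
  truth <- list(events = ev, n_events = n_ev,
                expected_events = rate * area * duration,
                fwhm_s = pulse_fwhm_s, radius_um = pulse_radius_um,
                propagation = propagation, generator = "pulses", seed = seed)
  list(movie = cw_movie(arr, dt, dx, "synthetic_pulses"), truth = truth)
}
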
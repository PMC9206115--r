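#' Explicit time-step stability bound and default step
#'
#' Forward Euler with the 5-point Laplacian is stable for
#' `dt <= dx^2 / (4 * D_max)`; the default step applies a 0.2 safety
#' factor to that bound and additionally caps `dt` at `0.05 / k_max`
#' (fastest first-order rate), whichever is smaller.
#'
#' @param p a [cw_params()] object.
#' @param dx lattice spacing (um).
#' @return A list with `dt_default` and `dt_max` (the hard bound).
#' @export
dt_bounds <- function(p, dx) {
  D_max <- max(p$D_RT, p$D_RD, p$D_F,
               if (!is.null(p$D_RDc)) p$D_RDc else 0)
  k_max <- max(unlist(p[c("k0", "k1", "k2", "k3", "k4", "k5", "k6", "k7",
                          "k8", "k9", "k10")]))
  dt_diff <- if (D_max > 0) dx^2 / (4 * D_max) else Inf
  list(dt_default = min(0.2 * dt_diff, 0.05 / k_max),
       dt_max = min(dt_diff, 0.5 / k_max))
}

#' Single forward-Euler step of the reduced model
#'
#' `state + dt * rhs_reduced(state, W, p)` followed by the non-negativity
#' floor.  Exactly reproducible given its inputs.
#'
#' @param state a [cw_state()].
#' @param W noise field (matrix or scalar 1).
#' @param p a [cw_params()] object.
#' @param dt time step (s); must satisfy the stability bound.
#' @param floor apply the non-negativity floor (default `TRUE`).
#' @return The updated [cw_state()].
#' @export
step <- function(state, W = 1, p, dt, floor = TRUE) {
  b <- dt_bounds(p, state$dx)
  if (dt > b$dt_max)
    stop("dt = ", dt, " exceeds the stability bound dt_max = ", b$dt_max,
         " = min(dx^2/(4 D_max), 0.5/k_max)")
  d <- rhs_reduced(state, W, p)
  upd <- function(x, dx_) if (floor) pmax(x + dt * dx_, 0) else x + dt * dx_
  out <- state
  out$RT <- upd(state$RT, d$dRT)
  out$RD <- upd(state$RD, d$dRD)
  out$F  <- upd(state$F, d$dF)
  out
}

#' Stochastic simulation of the reduced model on a periodic lattice
#'
#' Forward-Euler finite-difference integration with the multiplicative
#' noise field regenerated every `p$f` seconds (piecewise constant in
#' between).  The run is initialized at the canonical uniform steady state
#' (optionally perturbed) and is bit-reproducible given
#' `(params, grid, seed, dt)`.
#'
#' @param p a [cw_params()] object.
#' @param grid a [cw_grid()].
#' @param duration total simulated time (s).
#' @param dt time step (s); `NULL` uses the conservative default of
#'   [dt_bounds()].
#' @param sample_every sampling interval of stored frames (s).
#' @param seed integer seed controlling all randomness of the run.
#' @param init `"steady"` (exact uniform steady state), `"perturbed"`
#'   (steady state plus seeded Gaussian perturbation of relative amplitude
#'   `perturb_amp`), a [cw_state()], or `"mode"` (single cosine mode of
#'   wavevector index `mode_m` along x, amplitude `perturb_amp`, applied to
#'   all fields along the leading eigenvector direction of the reaction
#'   Jacobian).
#' @param perturb_amp relative perturbation amplitude.
#' @param mode_m integer mode index along x (for `init = "mode"`).
#' @param sigma_override optional noise sd overriding `p$sigma`.
#' @return An object of class `cw_trajectory`: list with `times`, `frames`
#'   (list of `RT`/`RD`/`F` matrices), `params`, `grid`, `seed`, `dt`.
#' @export
simulate <- function(p, grid, duration, dt = NULL, sample_every = 4,
                     seed = 1, init = "steady", perturb_amp = 1e-3,
                     mode_m = 1, sigma_override = NULL) {
  stopifnot(inherits(p, "cw_params"), inherits(grid, "cw_grid"))
  sigma <- if (is.null(sigma_override)) p$sigma else sigma_override
  b <- dt_bounds(p, grid$dx)
  if (is.null(dt)) dt <- b$dt_default
  if (dt > b$dt_max)
    stop("dt = ", dt, " exceeds the stability bound dt_max = ", b$dt_max)
  ssr <- pick_ss_row(uniform_steady_state(p))
  mk <- function(v) matrix(v, grid$ny, grid$nx)
  RT <- mk(ssr$RT_ss); RD <- mk(ssr$RD_ss); F <- mk(ssr$F_ss)
  set.seed(seed)
  if (inherits(init, "cw_state")) {
    RT <- init$RT; RD <- init$RD; F <- init$F
  } else if (identical(init, "perturbed")) {
    RT <- pmax(RT * (1 + perturb_amp * stats::rnorm(length(RT))), 0)
  } else if (identical(init, "mode")) {
    xs <- matrix(rep(seq_len(grid$nx) - 1, each = grid$ny), grid$ny)
    pert <- cos(2 * pi * mode_m * xs / grid$nx)
    RT <- pmax(RT + perturb_amp * ssr$RT_ss * pert, 0)
  } else if (!identical(init, "steady")) {
    stop("unknown init: ", init)
  }

  n_steps <- ceiling(duration / dt)
  steps_per_epoch <- max(1L, round(p$f / dt))
  steps_per_sample <- max(1L, round(sample_every / dt))
  times <- c()
  frames <- list()
  done <- 0L
  W <- if (sigma > 0) unclass(make_noise_field(grid, sigma, p$s))
       else matrix(1, grid$ny, grid$nx)
  while (done < n_steps) {
    to_epoch <- steps_per_epoch - (done %% steps_per_epoch)
    to_sample <- steps_per_sample - (done %% steps_per_sample)
    n <- min(to_epoch, to_sample, n_steps - done)
    out <- .cw_integrate_chunk(RT, RD, F, W, p, n, dt, grid$dx)
    RT <- out$RT; RD <- out$RD; F <- out$F
    done <- done + n
    if (done %% steps_per_sample == 0 || done == n_steps) {
      times <- c(times, done * dt)
      frames[[length(frames) + 1]] <- list(RT = RT, RD = RD, F = F)
    }
    if (done %% steps_per_epoch == 0 && sigma > 0)
      W <- unclass(make_noise_field(grid, sigma, p$s))
  }
  structure(list(times = times, frames = frames, params = p, grid = grid,
                 seed = seed, dt = dt, steady = ssr),
            class = "cw_trajectory")
}

#' Deterministic simulation of the full (membrane + cytoplasm) model
#'
#' R-level forward-Euler integration of the four-field model; intended for
#' conservation and reduction-limit checks on small lattices (for
#' production-scale stochastic runs use the reduced model and
#' [simulate()]).
#'
#' @param p a [cw_full_params()] object.
#' @param grid a [cw_grid()].
#' @param duration,dt,sample_every as in [simulate()].
#' @param init a [cw_state()] with `RDc`, or `"steady"` to start from the
#'   reduced-model canonical steady state with `RDc = RD0`.
#' @return A `cw_trajectory` whose frames carry `RDc` as well.
#' @export
simulate_full <- function(p, grid, duration, dt = NULL, sample_every = 4,
                          init = "steady") {
  stopifnot(inherits(p, "cw_full_params"))
  b <- dt_bounds(p, grid$dx)
  if (is.null(dt)) dt <- b$dt_default
  if (dt > b$dt_max) stop("dt exceeds stability bound ", b$dt_max)
  if (identical(init, "steady")) {
    ssr <- pick_ss_row(uniform_steady_state(reduce_full_params(p)))
    mk <- function(v) matrix(v, grid$ny, grid$nx)
    st <- cw_state(mk(ssr$RT_ss), mk(ssr$RD_ss), mk(ssr$F_ss),
                   RDc = mk(p$RD0), dx = grid$dx)
  } else st <- init
  n_steps <- ceiling(duration / dt)
  steps_per_sample <- max(1L, round(sample_every / dt))
  times <- c(); frames <- list()
  for (k in seq_len(n_steps)) {
    d <- rhs_full(st, 1, p)
    st$RT  <- pmax(st$RT + dt * d$dRT, 0)
    st$RD  <- pmax(st$RD + dt * d$dRD, 0)
    st$RDc <- pmax(st$RDc + dt * d$dRDc, 0)
    st$F   <- pmax(st$F + dt * d$dF, 0)
    if (k %% steps_per_sample == 0 || k == n_steps) {
      times <- c(times, k * dt)
      frames[[length(frames) + 1]] <-
        list(RT = st$RT, RD = st$RD, F = st$F, RDc = st$RDc)
    }
  }
  structure(list(times = times, frames = frames, params = p, grid = grid,
                 dt = dt), class = "cw_trajectory")
}

#' Convert a trajectory channel to a movie
#'
#' @param traj a `cw_trajectory`.
#' @param channel one of `"RT"`, `"RD"`, `"F"`.
#' @return A [cw_movie()] with `dt` equal to the sampling interval and `dx`
#'   the lattice spacing.
#' @export
as_movie <- function(traj, channel = "RT") {
  stopifnot(inherits(traj, "cw_trajectory"))
  nt <- length(traj$frames)
  f1 <- traj$frames[[1]][[channel]]
  arr <- array(0, c(nt, nrow(f1), ncol(f1)))
  for (k in seq_len(nt)) arr[k, , ] <- traj$frames[[k]][[channel]]
  dt_s <- if (nt > 1) stats::median(diff(traj$times)) else 1
  cw_movie(arr, dt = dt_s, dx = traj$grid$dx, channel = channel)
}

#' @export
print.cw_trajectory <- function(x, ...) {
  cat(sprintf("<cw_trajectory> %d frames, t in [%g, %g] s, %dx%d grid, dt=%g\n",
              length(x$frames), min(x$times), max(x$times),
              x$grid$ny, x$grid$nx, x$dt))
  invisible(x)
}
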
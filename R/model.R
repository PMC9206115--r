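#' Net Rho activation rate (reaction function)
#'
#' The reaction function couples autocatalytic GEF-dependent activation of
#' Rho with constitutive and F-actin-dependent inactivation:
#' \deqn{R = [k_0 + \alpha k_1 RT^3/(1 + k_2 RT^2)]\,RD -
#'       [k_3 + k_4 (1+\beta) F]\,RT.}
#' F-actin inhibits Rho even at `beta = 0` (the `k4*F` term), reflecting
#' GAP-independent inhibitory activity of the polymer or other
#' actin-binding proteins.
#'
#' @param rt,rd,f non-negative concentrations of active Rho, inactive
#'   membrane Rho and dynamic F-actin (scalars or arrays of one shape).
#' @param p a [cw_params()] object.
#' @return Net activation rate of `rt` (same shape as the inputs; may be
#'   negative).
#' @export
reaction_rate <- function(rt, rd, f, p) {
  if (any(rt < 0) || any(rd < 0) || any(f < 0))
    stop("concentrations must be non-negative")
  (p$k0 + p$alpha * p$k1 * rt^3 / (1 + p$k2 * rt^2)) * rd -
    (p$k3 + p$k4 * (1 + p$beta) * f) * rt
}

#' Net F-actin assembly rate
#'
#' Basal plus Rho-stimulated (saturating) assembly, minus first-order
#' disassembly modulated by the noise field `w` (deterministic kinetics for
#' `w = 1`):
#' \deqn{dF/dt = k_7 + k_8 RT^2/(1 + k_9 RT^2) - k_{10}\,w\,F.}
#'
#' @param rt,f non-negative concentrations.
#' @param w noise-field value(s), mean-1 field; use 1 for deterministic
#'   kinetics.
#' @param p a [cw_params()] object.
#' @return Net assembly rate of `f`.
#' @export
actin_rate <- function(rt, f, w = 1, p) {
  if (any(rt < 0) || any(f < 0))
    stop("concentrations must be non-negative")
  if (any(!is.finite(w))) stop("noise field must be finite")
  p$k7 + p$k8 * rt^2 / (1 + p$k9 * rt^2) - p$k10 * w * f
}

#' Lattice state of the reduced model
#'
#' Bundles the three concentration fields on a common 2D lattice.  Fields
#' may be scalars (spatially uniform state) or equal-shape matrices.
#'
#' @param RT,RD,F non-negative fields.
#' @param RDc optional cytoplasmic inactive-Rho field (full model only).
#' @param dx lattice spacing (um).
#' @return An object of class `cw_state`.
#' @export
cw_state <- function(RT, RD, F, RDc = NULL, dx = 1) {
  dims <- dim(as.matrix(RT))
  flds <- list(RT = RT, RD = RD, F = F)
  if (!is.null(RDc)) flds$RDc <- RDc
  for (nm in names(flds)) {
    fl <- as.matrix(flds[[nm]])
    if (!identical(dim(fl), dims)) stop("state fields must share one shape")
    if (any(!is.finite(fl))) stop("state field '", nm, "' has non-finite values")
    if (any(fl < 0)) stop("state field '", nm, "' has negative values")
    flds[[nm]] <- fl
  }
  structure(c(flds, list(dx = dx)), class = "cw_state")
}

#' Time derivative of the reduced model
#'
#' Evaluates the right-hand side of the membrane-only model: reaction
#' kinetics plus 5-point periodic Laplacian diffusion.  With all
#' diffusivities zero this reduces pointwise to [reaction_rate()] /
#' [actin_rate()] and the membrane exchange term `k5 - k6*RD`.
#'
#' @param state a [cw_state()].
#' @param W noise field (matrix matching the state shape, or scalar 1).
#' @param p a [cw_params()] object.
#' @return List of derivative fields `dRT`, `dRD`, `dF`.
#' @export
rhs_reduced <- function(state, W = 1, p) {
  if (is.matrix(W) && !identical(dim(W), dim(state$RT)))
    stop("noise field shape does not match state")
  R <- reaction_rate(state$RT, state$RD, state$F, p)
  dRT <- R
  dRD <- p$k5 - p$k6 * state$RD - R
  dF  <- actin_rate(state$RT, state$F, W, p)
  if (is.matrix(state$RT) && nrow(state$RT) > 1) {
    if (p$D_RT > 0) dRT <- dRT + p$D_RT * laplacian(state$RT, state$dx)
    if (p$D_RD > 0) dRD <- dRD + p$D_RD * laplacian(state$RD, state$dx)
    if (p$D_F  > 0) dF  <- dF  + p$D_F  * laplacian(state$F, state$dx)
  }
  list(dRT = dRT, dRD = dRD, dF = dF)
}

#' Time derivative of the full (membrane + cytoplasm) model
#'
#' Adds the reversible membrane/cytoplasm exchange of inactive Rho:
#' delivery `k5_star*RDc` onto the membrane and removal `k6*RD` back, with
#' the cytoplasmic balance scaled by the volume ratio `eta`.  The exchange
#' and reaction terms conserve the summed quantity `RT + RD + RDc/eta`.
#'
#' @param state a [cw_state()] carrying an `RDc` field.
#' @param W noise field or scalar 1.
#' @param p a [cw_full_params()] object.
#' @return List of derivative fields `dRT`, `dRD`, `dRDc`, `dF`.
#' @export
rhs_full <- function(state, W = 1, p) {
  stopifnot(inherits(p, "cw_full_params"))
  if (is.null(state$RDc)) stop("full-model state must carry an RDc field")
  if (p$eta == 0)
    stop("eta = 0 has no cytoplasmic dynamics; use rhs_reduced on ",
         "reduce_full_params(p)")
  R <- reaction_rate(state$RT, state$RD, state$F, p)
  dRT  <- R
  dRD  <- p$k5_star * state$RDc - p$k6 * state$RD - R
  dRDc <- p$eta * (p$k6 * state$RD - p$k5_star * state$RDc)
  dF   <- actin_rate(state$RT, state$F, W, p)
  if (is.matrix(state$RT) && nrow(state$RT) > 1) {
    if (p$D_RT > 0)  dRT  <- dRT  + p$D_RT  * laplacian(state$RT,  state$dx)
    if (p$D_RD > 0)  dRD  <- dRD  + p$D_RD  * laplacian(state$RD,  state$dx)
    if (p$D_RDc > 0) dRDc <- dRDc + p$D_RDc * laplacian(state$RDc, state$dx)
    if (p$D_F > 0)   dF   <- dF   + p$D_F   * laplacian(state$F,   state$dx)
  }
  list(dRT = dRT, dRD = dRD, dRDc = dRDc, dF = dF)
}

# Closed-form F nullcline and the scalar steady-state residual in RT.
# At any uniform fixed point the reaction function vanishes, which forces
# RD_ss = k5/k6; F_ss follows from RT in closed form, leaving one scalar
# equation in RT.
ss_fss <- function(rt, p) (p$k7 + p$k8 * rt^2 / (1 + p$k9 * rt^2)) / p$k10

ss_residual <- function(rt, p) {
  rd <- p$k5 / p$k6
  (p$k0 + p$alpha * p$k1 * rt^3 / (1 + p$k2 * rt^2)) * rd -
    (p$k3 + p$k4 * (1 + p$beta) * ss_fss(rt, p)) * rt
}

# long-time relaxation of the uniform kinetics from small positive
# concentrations, run through the compiled integrator on a tiny uniform
# lattice (diffusion is inert on a uniform field)
relax_uniform <- function(p, x0 = NULL, tmax = 4000) {
  if (is.null(x0)) x0 <- c(1e-3, p$k5 / p$k6, p$k7 / p$k10)
  k_max <- max(unlist(p[c("k0", "k1", "k2", "k3", "k4", "k5", "k6", "k7",
                          "k8", "k9", "k10")]))
  dt <- 0.05 / k_max
  mk <- function(v) matrix(v, 4, 4)
  out <- .cw_integrate_chunk(mk(x0[1]), mk(x0[2]), mk(x0[3]), mk(1),
                             p, ceiling(tmax / dt), dt, 1e6)
  c(out$RT[1], out$RD[1], out$F[1])
}

#' Uniform steady states of the reduced model
#'
#' Finds all non-negative spatially uniform fixed points of the
#' deterministic kinetics (`W = 1`).  `RD_ss = k5/k6` always, and `F_ss` is
#' a closed form of `RT_ss`, so roots are located by a sign-change scan of
#' the remaining scalar equation on a log-spaced `RT` grid followed by
#' bracketed polishing.  When several roots exist (excitable kinetics can
#' be multistable), all are returned and the one reached by relaxation from
#' small positive concentrations is flagged canonical.
#'
#' @param p a [cw_params()] object.
#' @param rt_range search range for `RT_ss` (log-spaced scan).
#' @param n_grid number of scan points.
#' @return An object of class `cw_steady_state`: a data frame with columns
#'   `RT_ss`, `RD_ss`, `F_ss`, `residual`, `stable_uniform` (reaction-only
#'   linear stability) and `canonical`.
#' @export
uniform_steady_state <- function(p, rt_range = c(1e-8, 1e4), n_grid = 4000) {
  stopifnot(inherits(p, "cw_params"))
  if (inherits(p, "cw_full_params")) p <- reduce_full_params(p)
  grid <- exp(seq(log(rt_range[1]), log(rt_range[2]), length.out = n_grid))
  if (p$k0 == 0) grid <- c(0, grid)  # RT = 0 is a root iff no basal activation
  v <- ss_residual(grid, p)
  roots <- numeric(0)
  sgn <- which(v[-length(v)] * v[-1] < 0)
  for (i in sgn)
    roots <- c(roots, stats::uniroot(ss_residual, c(grid[i], grid[i + 1]),
                                     p = p, tol = 1e-15)$root)
  if (p$k0 == 0 && abs(v[1]) < 1e-300) roots <- c(0, roots)
  roots <- sort(unique(roots))
  if (!length(roots))
    stop("no non-negative uniform steady state found in RT range [",
         rt_range[1], ", ", rt_range[2], "]; residual range [",
         min(v), ", ", max(v), "]")
  rd <- p$k5 / p$k6
  fs <- ss_fss(roots, p)
  resid <- vapply(roots, function(rt) {
    r <- abs(c(ss_residual(rt, p),
               p$k7 + p$k8 * rt^2 / (1 + p$k9 * rt^2) - p$k10 * ss_fss(rt, p)))
    max(r)
  }, 0)
  stab <- vapply(roots, function(rt) {
    all(Re(eigen(jacobian_at(rt, p), only.values = TRUE)$values) < 0)
  }, NA)
  canon <- if (length(roots) == 1) 1L else {
    xr <- relax_uniform(p)
    which.min(abs(roots - xr[1]))
  }
  out <- data.frame(RT_ss = roots, RD_ss = rd, F_ss = fs, residual = resid,
                    stable_uniform = stab,
                    canonical = seq_along(roots) == canon)
  class(out) <- c("cw_steady_state", "data.frame")
  out
}

# analytic reaction-only Jacobian at a uniform RT (RD, F at their nullclines)
jacobian_at <- function(rt, p) {
  rd <- p$k5 / p$k6
  f  <- ss_fss(rt, p)
  a_act  <- p$k0 + p$alpha * p$k1 * rt^3 / (1 + p$k2 * rt^2)
  da_act <- p$alpha * p$k1 * rt^2 * (3 + p$k2 * rt^2) / (1 + p$k2 * rt^2)^2
  B <- p$k3 + p$k4 * (1 + p$beta) * f
  dR_rt <- da_act * rd - B
  dR_rd <- a_act
  dR_f  <- -p$k4 * (1 + p$beta) * rt
  dG_rt <- 2 * p$k8 * rt / (1 + p$k9 * rt^2)^2
  matrix(c(dR_rt,  dR_rd,        dR_f,
           -dR_rt, -p$k6 - dR_rd, -dR_f,
           dG_rt,  0,            -p$k10),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("RT", "RD", "F"), c("RT", "RD", "F")))
}

#' Reaction-only Jacobian at a uniform steady state
#'
#' Analytic linearization of the spatially uniform deterministic kinetics
#' around a fixed point, used by the dispersion analysis.
#'
#' @param p a [cw_params()] object.
#' @param ss a row of [uniform_steady_state()] output (or the whole object,
#'   in which case the canonical root is used).
#' @return A 3x3 matrix with rows/columns ordered (`RT`, `RD`, `F`).
#' @export
jacobian <- function(p, ss = uniform_steady_state(p)) {
  row <- pick_ss_row(ss)
  if (row$residual > 1e-8)
    stop("steady-state residual ", row$residual,
         " exceeds 1e-8; not a fixed point")
  jacobian_at(row$RT_ss, p)
}

#' Canonical steady-state root
#'
#' Convenience accessor: the row of a [uniform_steady_state()] result
#' flagged as reached by relaxation from small positive concentrations.
#'
#' @param ss a `cw_steady_state` object.
#' @return A one-row data frame.
#' @export
pick_canonical <- function(ss) {
  stopifnot(inherits(ss, "cw_steady_state"))
  ss[which(ss$canonical), , drop = FALSE]
}

pick_ss_row <- function(ss) {
  if (inherits(ss, "cw_steady_state")) ss[which(ss$canonical), , drop = FALSE]
  else ss
}

#' @export
print.cw_steady_state <- function(x, ...) {
  cat("<cw_steady_state> (", nrow(x), " root", if (nrow(x) > 1) "s", ")\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
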
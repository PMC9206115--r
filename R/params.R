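#' Model parameters for the reduced cortical excitability circuit
#'
#' Container for the rate constants, feedback strengths, diffusivities and
#' noise parameters of the reduced (membrane-only) three-field model of
#' cortical Rho/F-actin dynamics.  Time is in seconds, space in micrometres,
#' concentrations are nondimensional.
#'
#' The default values are a calibrated set: with `alpha = 1` and `beta`
#' swept upward they place the uniform steady state successively in the
#' higher uniform state, the wave-instability domain (most unstable
#' wavelength about 20 um, period about 30 s), the oscillatory domain, and
#' the lower uniform state, matching the scales of cortical waves in
#' immature frog oocytes.
#'
#' @param k0 basal Rho activation rate (1/s).
#' @param k1 autocatalytic (GEF-dependent) activation coefficient.
#' @param k2 activation saturation coefficient.
#' @param k3 constitutive Rho inactivation rate (1/s).
#' @param k4 F-actin-dependent inactivation coefficient.
#' @param k5 net Rho delivery rate onto the membrane (conc/s).
#' @param k6 membrane Rho removal rate (1/s).
#' @param k7 basal F-actin assembly rate (conc/s).
#' @param k8 Rho-stimulated F-actin assembly coefficient.
#' @param k9 F-actin assembly saturation coefficient.
#' @param k10 F-actin disassembly rate (1/s).
#' @param alpha nondimensional effective GEF (Ect2) level.
#' @param beta nondimensional effective GAP (RGA-3/4) level.
#' @param D_RT,D_RD,D_F diffusivities of active Rho, inactive membrane Rho
#'   and dynamic F-actin (um^2/s); `D_RT <= D_RD` is enforced.
#' @param sigma standard deviation of the mean-1 multiplicative noise field.
#' @param s spatial correlation length of the noise field (um).
#' @param f regeneration interval of the noise field (s).
#' @return An object of class `cw_params` (a validated named list).
#' @examples
#' p <- cw_params()
#' p$beta <- 0.8
#' uniform_steady_state(p)
#' @export
cw_params <- function(k0 = 0.08, k1 = 4, k2 = 2.2, k3 = 0.4, k4 = 0.135,
                      k5 = 0.5, k6 = 0.5, k7 = 0.018, k8 = 0.5, k9 = 0.4,
                      k10 = 0.11, alpha = 1, beta = 0,
                      D_RT = 0.9, D_RD = 9, D_F = 0.09,
                      sigma = 0.15, s = 2, f = 10) {
  p <- list(k0 = k0, k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
            k7 = k7, k8 = k8, k9 = k9, k10 = k10, alpha = alpha, beta = beta,
            D_RT = D_RT, D_RD = D_RD, D_F = D_F, sigma = sigma, s = s, f = f)
  validate_params(p)
  structure(p, class = "cw_params")
}

#' Parameters for the full (membrane + cytoplasm) model
#'
#' Extends [cw_params()] with the membrane/cytoplasm exchange parameters:
#' `k5_star` (cytoplasm-to-membrane delivery rate, 1/s), `RD0` (cytoplasmic
#' inactive-Rho concentration), `eta` (membrane/cytoplasm volume ratio) and
#' `D_RDc` (cytoplasmic diffusivity, um^2/s).  In the limit `eta -> 0` with
#' `RDc = RD0` the full model reduces to the membrane-only model with
#' `k5 = k5_star * RD0` (see [reduce_full_params()]).
#'
#' The default `eta` is the frog-oocyte estimate 5e-5 (a quoted constant,
#' not derived here).
#'
#' @inheritParams cw_params
#' @param k5_star cytoplasm-to-membrane delivery rate (1/s).
#' @param RD0 cytoplasmic inactive-Rho concentration.
#' @param eta membrane/cytoplasm volume ratio (dimensionless).
#' @param D_RDc cytoplasmic inactive-Rho diffusivity (um^2/s).
#' @param ... further arguments passed to [cw_params()].
#' @return An object of class `c("cw_full_params", "cw_params")`.
#' @export
cw_full_params <- function(k5_star = 1, RD0 = 0.5, eta = 5e-5, D_RDc = 9,
                           ...) {
  base <- cw_params(...)
  base$k5 <- k5_star * RD0   # keep the reduced-model consistency k5 = k5*.RD0
  p <- c(unclass(base),
         list(k5_star = k5_star, RD0 = RD0, eta = eta, D_RDc = D_RDc))
  if (eta < 0 || k5_star < 0 || RD0 < 0 || D_RDc < 0)
    stop("k5_star, RD0, eta and D_RDc must be non-negative")
  structure(p, class = c("cw_full_params", "cw_params"))
}

validate_params <- function(p) {
  rates <- c("k0", "k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9", "k10")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0 ||
        !is.finite(p[[nm]]))
      stop("rate constant '", nm, "' must be a single non-negative number")
  if (p$alpha < 0 || p$beta < 0)
    stop("alpha and beta must be non-negative")
  if (p$D_RT < 0 || p$D_RD < 0 || p$D_F < 0)
    stop("diffusivities must be non-negative")
  if (p$D_RT > p$D_RD)
    stop("D_RT must not exceed D_RD (active Rho diffuses slower)")
  if (p$sigma < 0) stop("sigma must be non-negative")
  if (p$s <= 0) stop("noise correlation length s must be positive")
  if (p$f <= 0) stop("noise regeneration interval f must be positive")
  invisible(p)
}

#' Reduce full-model parameters to the membrane-only model
#'
#' Applies the small-volume-ratio limit: the cytoplasmic pool is clamped at
#' `RD0` so the membrane delivery flux becomes the constant `k5 =
#' k5_star * RD0`; membrane diffusivities carry over unchanged.
#'
#' @param p a [cw_full_params()] object.
#' @return A [cw_params()] object with `k5 = k5_star * RD0`.
#' @export
reduce_full_params <- function(p) {
  stopifnot(inherits(p, "cw_full_params"))
  q <- unclass(p)
  q$k5 <- p$k5_star * p$RD0
  q[c("k5_star", "RD0", "eta", "D_RDc")] <- NULL
  structure(q, class = "cw_params")
}

PARAM_KEYS <- c("k0", "k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9",
                "k10", "alpha", "beta", "D_RT", "D_RD", "D_F", "sigma", "s",
                "f")
FULL_KEYS <- c(PARAM_KEYS, "k5_star", "RD0", "eta", "D_RDc")

#' Read a parameter set from YAML or JSON
#'
#' The file must contain only the canonical keys `k0`...`k10`, `alpha`,
#' `beta`, `D_RT`, `D_RD`, `D_F`, `sigma`, `s`, `f` (plus `k5_star`, `RD0`,
#' `eta`, `D_RDc` for the full model); unknown keys are rejected.  Missing
#' keys fall back to the calibrated defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [cw_params()] or [cw_full_params()] object.
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unrecognized parameter file extension (want .yaml/.yml/.json): ",
            path)
  full <- any(c("k5_star", "RD0", "eta", "D_RDc") %in% names(vals))
  allowed <- if (full) FULL_KEYS else PARAM_KEYS
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         "; allowed keys are: ", paste(allowed, collapse = ", "))
  vals <- lapply(vals, as.numeric)
  do.call(if (full) cw_full_params else cw_params, vals)
}

#' Write a parameter set to YAML or JSON
#' @param p a [cw_params()] object.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "cw_params"))
  vals <- unclass(p)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(vals, path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else stop("unrecognized parameter file extension: ", path)
  invisible(path)
}

#' @export
print.cw_params <- function(x, ...) {
  kind <- if (inherits(x, "cw_full_params")) "full" else "reduced"
  cat(sprintf("<cw_params (%s model)>\n", kind))
  keys <- intersect(if (kind == "full") FULL_KEYS else PARAM_KEYS, names(x))
  cat(paste(sprintf("  %-7s %g", keys, unlist(x[keys])), collapse = "\n"),
      "\n")
  invisible(x)
}
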
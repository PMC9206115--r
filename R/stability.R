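#' Dispersion relation of the uniform steady state
#'
#' For each wavenumber `q` the growth rates are the eigenvalues of
#' `J - q^2 diag(D_RT, D_RD, D_F)`, with `J` the reaction-only Jacobian at
#' the canonical uniform steady state.  A positive real part at some
#' `q > 0` with nonzero imaginary part signals the finite-wavenumber
#' oscillatory (wave) instability, the travelling-wave analogue of the
#' Turing mechanism.
#'
#' @param p a [cw_params()] object.
#' @param qs non-negative wavenumbers (1/um).  Defaults to `q = 0` plus 200
#'   log-spaced points bracketing all modes resolvable on a default-scale
#'   lattice (`L = 204.8` um, `dx = 0.8` um).
#' @param ss optional precomputed [uniform_steady_state()].
#' @return An object of class `cw_dispersion`: list with `q`, a complex
#'   `length(q) x 3` matrix `eigenvalues` (each row sorted by decreasing
#'   real part), `max_re`, `im_at_max`, and `q_star` (wavenumber of the
#'   largest positive growth rate; `NA` if all modes are stable).
#' @export
dispersion <- function(p, qs = default_q_grid(), ss = uniform_steady_state(p)) {
  if (!length(qs)) stop("empty wavenumber list")
  if (any(qs < 0)) stop("wavenumbers must be non-negative")
  J <- jacobian(p, ss)
  Dv <- c(p$D_RT, p$D_RD, p$D_F)
  ev <- t(vapply(qs, function(q) {
    e <- eigen(J - q^2 * diag(Dv), only.values = TRUE)$values
    e[order(-Re(e))]
  }, complex(3)))
  max_re <- Re(ev[, 1])
  im_at_max <- abs(Im(ev[, 1]))
  iq <- which.max(max_re)
  q_star <- if (max_re[iq] > 0) qs[iq] else NA_real_
  structure(list(q = qs, eigenvalues = ev, max_re = max_re,
                 im_at_max = im_at_max, q_star = q_star,
                 ss = pick_ss_row(ss)),
            class = "cw_dispersion")
}

default_q_grid <- function(L = 204.8, dx = 0.8, n = 200) {
  c(0, exp(seq(log(2 * pi / L), log(2 * pi / (2 * dx)), length.out = n)))
}

#' Classify the dynamical regime of a parameter set
#'
#' Labels the canonical uniform steady state as one of
#' `"higher_uniform"`, `"wave_instability"`, `"oscillatory"` or
#' `"lower_uniform"`:
#' * `oscillatory` - unstable at `q = 0` with complex growth rate (also
#'   chosen when both `q = 0` and finite `q` are unstable);
#' * `wave_instability` - stable at `q = 0` but a finite-`q` mode grows
#'   with nonzero frequency;
#' * otherwise a stable uniform state, split into higher/lower by
#'   comparing `RT_ss` against the midpoint of the unstable window of an
#'   internal beta scan (high-Rho zone 1 vs low-Rho zone 2).
#'
#' @param p a [cw_params()] object.
#' @param qs wavenumber grid (see [dispersion()]).
#' @param rt_split optional reference `RT` separating the higher from the
#'   lower uniform state; computed from an internal coarse beta scan when
#'   `NULL`.
#' @param tol instability tolerance on `Re(lambda)`.
#' @return A length-1 character label with attributes `dispersion` (the
#'   [dispersion()] result) and `RT_ss`.
#' @export
classify_regime <- function(p, qs = default_q_grid(), rt_split = NULL,
                            tol = 1e-9) {
  d <- dispersion(p, qs)
  re0 <- d$max_re[d$q == 0]
  im0 <- d$im_at_max[d$q == 0]
  iq <- which.max(d$max_re)
  lab <- if (length(re0) && re0 > tol) {
    if (im0 <= tol)
      stop("unstable q=0 mode is non-oscillatory at tolerance ", tol,
           "; classification ambiguous (see attached dispersion)")
    "oscillatory"
  } else if (d$max_re[iq] > tol) {
    if (d$im_at_max[iq] <= tol)
      stop("finite-q instability is stationary (Turing-like), outside the ",
           "four-regime set; see attached dispersion")
    "wave_instability"
  } else {
    if (is.null(rt_split)) rt_split <- uniform_split_rt(p)
    if (d$ss$RT_ss >= rt_split) "higher_uniform" else "lower_uniform"
  }
  attr(lab, "dispersion") <- d
  attr(lab, "RT_ss") <- d$ss$RT_ss
  lab
}

# Reference RT separating zone 1 (high Rho) from zone 2 (low Rho): the
# canonical RT_ss at the midpoint of the unstable (wave/oscillatory) window
# of a coarse internal beta scan; when no instability exists anywhere
# (e.g. alpha = 0), fall back to the geometric mean of the end states.
uniform_split_rt <- function(p, beta_span = c(1e-3, 1e3), n_scan = 25) {
  bgrid <- exp(seq(log(beta_span[1]), log(beta_span[2]), length.out = n_scan))
  rts <- numeric(n_scan); unst <- logical(n_scan)
  for (i in seq_along(bgrid)) {
    p$beta <- bgrid[i]
    row <- pick_ss_row(uniform_steady_state(p))
    rts[i] <- row$RT_ss
    d <- dispersion(p, ss = row)
    unst[i] <- max(d$max_re) > 1e-9
  }
  if (any(unst)) {
    w <- range(which(unst))
    mid <- round(mean(w))
    # midpoint state of the unstable window; average with neighbours for
    # robustness against multistable folds at the window edge
    exp(mean(log(pmax(rts[max(1, mid - 1):min(n_scan, mid + 1)], 1e-12))))
  } else {
    sqrt(prod(pmax(rts[c(1, n_scan)], 1e-12)))
  }
}

#' Regime diagram along the negative-feedback axis
#'
#' Classifies every value of a strictly increasing `beta` grid at fixed
#' `alpha` and refines each regime boundary by bisection to a relative
#' tolerance.  With the calibrated defaults the succession is
#' `higher_uniform -> wave_instability -> oscillatory -> lower_uniform`.
#'
#' @param p a [cw_params()] object (its `beta` is ignored).
#' @param betas strictly increasing grid of RGA-3/4 levels.
#' @param qs wavenumber grid.
#' @param refine_tol relative tolerance of the bisection refinement.
#' @return An object of class `cw_regime_diagram`: data frame with columns
#'   `beta`, `regime`, `RT_ss`, `max_re_lambda`, `q_star`, plus an attribute
#'   `boundaries` (data frame of refined `beta` values where the label
#'   changes).
#' @export
beta_scan <- function(p, betas, qs = default_q_grid(), refine_tol = 1e-3) {
  if (is.unsorted(betas, strictly = TRUE))
    stop("betas must be strictly increasing")
  rt_split <- uniform_split_rt(p)
  one <- function(b) {
    p$beta <- b
    lab <- classify_regime(p, qs, rt_split = rt_split)
    d <- attr(lab, "dispersion")
    data.frame(beta = b, regime = as.character(lab), RT_ss = d$ss$RT_ss,
               max_re_lambda = max(d$max_re),
               q_star = if (is.na(d$q_star)) NA_real_ else d$q_star)
  }
  rows <- do.call(rbind, lapply(betas, one))
  bounds <- NULL
  if (length(betas) > 1) {
    for (i in seq_len(length(betas) - 1)) {
      if (rows$regime[i] == rows$regime[i + 1]) next
      lo <- betas[i]; hi <- betas[i + 1]
      lab_lo <- rows$regime[i]
      while ((hi - lo) / hi > refine_tol) {
        mid <- sqrt(lo * hi)
        lab_mid <- tryCatch(
          as.character(classify_regime(`$<-`(p, "beta", mid), qs,
                                       rt_split = rt_split)),
          error = function(e) NA_character_)
        if (identical(lab_mid, lab_lo)) lo <- mid else hi <- mid
      }
      bounds <- rbind(bounds,
                      data.frame(beta = sqrt(lo * hi),
                                 from = rows$regime[i], to = rows$regime[i + 1]))
    }
  }
  structure(rows, boundaries = bounds,
            class = c("cw_regime_diagram", "data.frame"))
}

#' @export
print.cw_regime_diagram <- function(x, ...) {
  cat("<cw_regime_diagram>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  b <- attr(x, "boundaries")
  if (!is.null(b)) {
    cat("boundaries:\n")
    print.data.frame(b, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
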
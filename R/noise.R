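#' Periodic simulation lattice
#'
#' @param nx,ny lattice sizes (at least 8).
#' @param dx spacing (um).  Boundaries are always periodic.
#' @return An object of class `cw_grid`.
#' @export
cw_grid <- function(nx = 256, ny = nx, dx = 0.8) {
  if (nx < 8 || ny < 8) stop("lattice must be at least 8x8")
  if (dx <= 0) stop("dx must be positive")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 periodic = TRUE), class = "cw_grid")
}

#' Spatially correlated mean-1 Gaussian noise field
#'
#' White Gaussian noise is convolved (via FFT, periodically) with a
#' Gaussian kernel of standard deviation `s`, then affinely renormalized so
#' the sample mean is exactly 1 and the sample standard deviation exactly
#' `sigma`.  With this construction the spatial autocorrelation is Gaussian
#' with e-folding distance `2*s` (the adopted definition of the correlation
#' length).  The field is deterministic given the R RNG state.
#'
#' @param grid a [cw_grid()].
#' @param sigma target standard deviation (0 gives the constant field 1).
#' @param s correlation length (um); a warning is attached when `s < dx`
#'   (unresolvable on the lattice).
#' @return A `ny x nx` matrix of class `cw_noise_field` with attributes
#'   `sigma`, `s`.
#' @export
make_noise_field <- function(grid, sigma, s) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (s <= 0) stop("correlation length must be positive")
  W <- matrix(1, grid$ny, grid$nx)
  if (sigma > 0) {
    z <- matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx)
    z <- gaussian_blur_periodic(z, s / grid$dx)
    z <- z - mean(z)
    sdz <- stats::sd(as.vector(z))
    if (sdz == 0) stop("degenerate noise field")
    # exact affine renormalization (sample moments, denominator n)
    n <- length(z)
    sdn <- sqrt(sum(z^2) / n)
    W <- 1 + z * (sigma / sdn)
  }
  out <- structure(W, class = c("cw_noise_field", "matrix", "array"),
                   sigma = sigma, s = s)
  if (s < grid$dx)
    attr(out, "warning") <- "correlation length below lattice spacing"
  out
}

# periodic Gaussian convolution via FFT; sd_px in lattice units
gaussian_blur_periodic <- function(z, sd_px) {
  ny <- nrow(z); nx <- ncol(z)
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  # transfer function of a Gaussian kernel: exp(-2 pi^2 sd^2 k^2)
  gy <- exp(-2 * pi^2 * sd_px^2 * ky^2)
  gx <- exp(-2 * pi^2 * sd_px^2 * kx^2)
  H <- outer(gy, gx)
  Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (ny * nx)
}

#' 5-point periodic Laplacian
#'
#' Second-order finite-difference Laplacian with periodic wraparound; the
#' lattice sum of the result vanishes to roundoff (discrete divergence
#' theorem on the torus).
#'
#' @param field a matrix (at least 2x2).
#' @param dx lattice spacing.
#' @return Matrix of the same shape.
#' @export
laplacian <- function(field, dx = 1) {
  if (!is.matrix(field) || nrow(field) < 2 || ncol(field) < 2)
    stop("field must be a matrix of at least 2x2")
  up    <- field[c(nrow(field), seq_len(nrow(field) - 1)), , drop = FALSE]
  down  <- field[c(seq_len(nrow(field))[-1], 1), , drop = FALSE]
  left  <- field[, c(ncol(field), seq_len(ncol(field) - 1)), drop = FALSE]
  right <- field[, c(seq_len(ncol(field))[-1], 1), drop = FALSE]
  (up + down + left + right - 4 * field) / dx^2
}
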
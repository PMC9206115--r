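#' Time-lapse movie container
#'
#' A `(time, y, x)` intensity stack with physical calibration, the common
#' currency of the quantification pipeline (works identically for
#' experimental stacks and simulated trajectories).
#'
#' @param data numeric array `(nt, ny, nx)` with at least 8 frames.
#' @param dt frame interval (s).
#' @param dx pixel size (um).
#' @param channel label (e.g. `"RT"`, `"rGBD"`).
#' @return An object of class `cw_movie`.
#' @export
cw_movie <- function(data, dt, dx, channel = "intensity") {
  if (length(dim(data)) != 3) stop("movie data must be a (time, y, x) array")
  if (dim(data)[1] < 8) stop("movie must have at least 8 frames")
  if (dt <= 0 || dx <= 0) stop("dt and dx must be positive")
  if (any(!is.finite(data))) stop("movie contains non-finite values")
  structure(list(data = data, dt = dt, dx = dx, channel = channel),
            class = "cw_movie")
}

#' @export
print.cw_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cw_movie '%s'> %d frames of %dx%d px; dt=%g s, dx=%g um\n",
              x$channel, d[1], d[2], d[3], x$dt, x$dx))
  invisible(x)
}

#' Box-averaged signal matrix
#'
#' Divides each frame into square boxes of `box_px` pixels and spatially
#' averages the signal within each box, yielding the matrix `J(i, j, k)` of
#' per-box traces.  Trailing partial boxes at the frame edge are dropped so
#' every trace aggregates the same number of pixels.
#'
#' @param movie a [cw_movie()].
#' @param box_px box edge in pixels (the classic choice is 15 px = 4 um at
#'   0.267 um/px).
#' @return An object of class `cw_box_series`: list with array `J`
#'   `(n_boxes_y, n_boxes_x, nt)`, `box_px` and `box_um`.
#' @export
box_average <- function(movie, box_px = 15) {
  stopifnot(inherits(movie, "cw_movie"))
  d <- dim(movie$data)
  if (box_px < 1 || box_px > d[2] || box_px > d[3])
    stop("box_px must be between 1 and the frame dimensions")
  ni <- d[2] %/% box_px
  nj <- d[3] %/% box_px
  cropped <- movie$data[, seq_len(ni * box_px), seq_len(nj * box_px),
                        drop = FALSE]
  # average within boxes: reshape (t, i, bi, j, bj) and mean over (bi, bj)
  dim(cropped) <- c(d[1], box_px, ni, box_px, nj)
  J <- apply(cropped, c(3, 5, 1), mean)
  structure(list(J = J, box_px = box_px, box_um = box_px * movie$dx,
                 dt = movie$dt), class = "cw_box_series")
}

#' Normalize a trace to the unit interval
#'
#' The affine map `(y - min) / (max - min)`: lowest point 0, highest 1.
#'
#' @param trace numeric vector, non-constant.
#' @return The normalized trace.
#' @export
normalize01 <- function(trace) {
  r <- range(trace)
  if (r[1] == r[2]) stop("flat signal")
  (trace - r[1]) / (r[2] - r[1])
}

# mean-removed autocorrelation normalized by lag 0, lags 0..(n-1)
autocorr_full <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  r <- vapply(0:(n - 1), function(l)
    sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]), 0)
  if (r[1] == 0) return(rep(NA_real_, n))
  r / r[1]
}

# first local maximum (index > 1) with prominence >= prom over the running
# minimum since lag 0 AND value above the white-noise floor for that lag
# (3 standard errors of a noise autocorrelation, sqrt(n - lag)/n);
# returns index into r or NA
first_prominent_max <- function(r, prom = 0.05) {
  n <- length(r)
  if (n < 3) return(NA_integer_)
  run_min <- cummin(r)
  for (k in 2:(n - 1)) {
    if (r[k] > r[k - 1] && r[k] >= r[k + 1] &&
        r[k] - run_min[k] >= prom &&
        r[k] >= 3 * sqrt(n - k + 1) / n) return(k)
  }
  NA_integer_
}

#' Oscillation period from the autocorrelation function
#'
#' The period is the lag of the first local maximum of the mean-removed,
#' lag-0-normalized autocorrelation at positive lag, subject to a
#' prominence threshold (rise above the running minimum) that rejects
#' noise-only traces.  Returns `NA` when no qualifying maximum exists or
#' the record is shorter than three putative cycles.
#'
#' @param trace numeric vector.
#' @param dt sampling interval (s).
#' @param prominence minimum rise of the autocorrelation above its running
#'   minimum (default 0.05); an adaptive white-noise floor `3/sqrt(n)` is
#'   applied on top, so short noise-only records report no period.
#' @return Period in seconds, or `NA_real_`.
#' @export
period_autocorr <- function(trace, dt, prominence = 0.05) {
  if (stats::sd(trace) == 0) return(NA_real_)
  r <- autocorr_full(trace)
  k <- first_prominent_max(r, prominence)
  if (is.na(k)) return(NA_real_)
  period <- (k - 1) * dt
  if (length(trace) * dt < 3 * period) return(NA_real_)  # < 3 cycles
  period
}

#' Signal shift from the cross-correlation function
#'
#' Lag of the cross-correlation maximum nearest zero (among prominent local
#' maxima), positive when `b` trails `a`.
#'
#' @param a,b equal-length, non-constant numeric traces.
#' @param dt sampling interval (s).
#' @param max_lag optional largest |lag| (samples) searched.
#' @return Lag in seconds (positive: `b` delayed relative to `a`).
#' @export
xcorr_shift <- function(a, b, dt, max_lag = NULL) {
  if (length(a) != length(b)) stop("traces must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant input trace")
  n <- length(a)
  if (is.null(max_lag)) max_lag <- n - 2L
  a <- a - mean(a); b <- b - mean(b)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(l) {
    # r(l) = sum_t a(t) b(t + l): peaks at l = tau when b(t) = a(t - tau)
    if (l >= 0) sum(a[seq_len(n - l)] * b[seq_len(n - l) + l]) /
      (n - abs(l))
    else sum(b[seq_len(n + l)] * a[seq_len(n + l) - l]) / (n - abs(l))
  }, 0)
  # local maxima; pick the one nearest zero lag, ties favour positive lag
  i0 <- which(lags == 0)
  cand <- which(diff(sign(diff(r))) < 0) + 1L
  if (r[1] > r[2]) cand <- c(1L, cand)
  if (r[length(r)] > r[length(r) - 1]) cand <- c(cand, length(r))
  if (!length(cand)) return(0)
  best <- cand[order(abs(lags[cand]), -lags[cand])][1]
  lags[best] * dt
}

# local maxima of a trace with prominence >= prom_frac * range; returns
# data.frame(idx, height, prominence)
find_peaks <- function(x, prom_frac = 0.1) {
  n <- length(x)
  rng <- diff(range(x))
  if (rng == 0) return(data.frame(idx = integer(), height = numeric(),
                                  prominence = numeric()))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(idx)) return(data.frame(idx = integer(), height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(k) {
    left <- if (any(x[seq_len(k - 1)] > x[k])) {
      j <- max(which(x[seq_len(k - 1)] > x[k]))
      min(x[j:k])
    } else min(x[seq_len(k)])
    right <- if (any(x[(k + 1):n] > x[k]) && k < n) {
      j <- k + min(which(x[(k + 1):n] > x[k]))
      min(x[k:j])
    } else min(x[k:n])
    x[k] - max(left, right)
  }, 0)
  keep <- prom >= prom_frac * rng
  data.frame(idx = idx[keep], height = x[idx[keep]],
             prominence = prom[keep])
}

#' Mean temporal width (FWHM) of wave peaks
#'
#' Detects local maxima passing a prominence threshold and measures each
#' peak's full width at half its prominence height (the half-height width
#' of the peak above its own base), interpolating the crossings linearly;
#' widths are averaged over the detected peaks.
#'
#' @param trace numeric vector.
#' @param dt sampling interval (s).
#' @param prom_frac prominence threshold as a fraction of the trace range.
#' @return Mean FWHM (s), or `NA_real_` if no peak qualifies.
#' @export
temporal_width <- function(trace, dt, prom_frac = 0.1) {
  pk <- find_peaks(trace, prom_frac)
  if (!nrow(pk)) return(NA_real_)
  n <- length(trace)
  widths <- vapply(seq_len(nrow(pk)), function(r) {
    k <- pk$idx[r]
    href <- pk$height[r] - pk$prominence[r] / 2
    # walk left
    i <- k; while (i > 1 && trace[i - 1] >= href && trace[i - 1] <= trace[i]) i <- i - 1
    tl <- if (i == 1 || trace[i - 1] > trace[i]) i - 1
          else (i - 1) - (href - trace[i]) / (trace[i - 1] - trace[i])
    j <- k; while (j < n && trace[j + 1] >= href && trace[j + 1] <= trace[j]) j <- j + 1
    tr <- if (j == n || trace[j + 1] > trace[j]) j - 1
          else (j - 1) + (trace[j] - href) / (trace[j] - trace[j + 1])
    (tr - tl) * dt
  }, 0)
  mean(widths)
}

#' Relative wave amplitude of a trace
#'
#' The max-minus-min excursion inside a moving window of about one
#' oscillation period, averaged over all window positions, normalized by
#' the trace minimum (the change above background,
#' `(signal_max - signal_min)/signal_min`, measured windowed so slow
#' baseline drift does not inflate it).
#'
#' @param trace strictly positive numeric vector.
#' @param dt sampling interval (s).
#' @param window_s window length (s); defaults to the measured
#'   autocorrelation period (falling back to the whole trace if no period
#'   is detected).
#' @param normalize `"min"` (default; divide the mean excursion by the
#'   trace minimum, the change-above-background ratio) or `"none"` (the
#'   raw mean windowed excursion, in intensity units).
#' @return Relative amplitude (dimensionless for `"min"`, >= 0).
#' @export
relative_amplitude <- function(trace, dt, window_s = NULL,
                               normalize = c("min", "none")) {
  normalize <- match.arg(normalize)
  if (normalize == "min" && min(trace) <= 0)
    stop("relative amplitude requires a strictly positive trace")
  if (is.null(window_s)) window_s <- period_autocorr(trace, dt)
  if (is.na(window_s)) window_s <- length(trace) * dt
  w <- max(2L, min(length(trace), round(window_s / dt) + 1L))
  n <- length(trace)
  exc <- vapply(seq_len(n - w + 1L), function(i) {
    win <- trace[i:(i + w - 1L)]
    max(win) - min(win)
  }, 0)
  if (normalize == "min") mean(exc) / min(trace) else mean(exc)
}

#' Kymograph along a 1-pixel line
#'
#' Reslices the movie along a fixed row or column: the result is a
#' `(time x position)` image whose stripe slope is the wave speed.
#'
#' @param movie a [cw_movie()].
#' @param line index of the row (`axis = "row"`) or column
#'   (`axis = "col"`) to extract.
#' @param axis `"row"` (line along x) or `"col"` (line along y).
#' @return A matrix of class `cw_kymograph` (rows = frames) with attributes
#'   `dt`, `dx`.
#' @export
kymograph <- function(movie, line, axis = c("row", "col")) {
  stopifnot(inherits(movie, "cw_movie"))
  axis <- match.arg(axis)
  d <- dim(movie$data)
  nmax <- if (axis == "row") d[2] else d[3]
  if (line < 1 || line > nmax) stop("line index out of bounds")
  img <- if (axis == "row") movie$data[, line, ] else movie$data[, , line]
  structure(img, class = c("cw_kymograph", "matrix", "array"),
            dt = movie$dt, dx = movie$dx)
}

#' Whole-movie wave metrics
#'
#' Runs the full box pipeline: box-average the movie(s), compute per-box
#' period, temporal width and relative amplitude (and, when a second
#' channel is given, the cross-correlation shift of channel b relative to
#' channel a), and aggregate means and standard deviations over all boxes
#' with a defined value.
#'
#' @param movie_a a [cw_movie()].
#' @param movie_b optional second channel of identical geometry (the
#'   follower; positive shift means b trails a).
#' @param box_px box edge in pixels.
#' @param prominence autocorrelation prominence threshold.
#' @param amplitude_normalize amplitude convention passed to
#'   [relative_amplitude()] (`"min"` ratio form by default).
#' @return An object of class `cw_metrics`: list with `per_box` (data frame
#'   of box metrics) and `summary` (means, SDs, `n_boxes_used`,
#'   provenance).
#' @export
summarize <- function(movie_a, movie_b = NULL, box_px = 15,
                      prominence = 0.05,
                      amplitude_normalize = c("min", "none")) {
  amplitude_normalize <- match.arg(amplitude_normalize)
  stopifnot(inherits(movie_a, "cw_movie"))
  if (!is.null(movie_b)) {
    stopifnot(inherits(movie_b, "cw_movie"))
    if (!identical(dim(movie_a$data), dim(movie_b$data)))
      stop("channel shape mismatch")
  }
  bs <- box_average(movie_a, box_px)
  bs_b <- if (!is.null(movie_b)) box_average(movie_b, box_px)
  dims <- dim(bs$J)
  dt <- movie_a$dt
  periods <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    tr <- bs$J[i, j, ]
    if (stats::sd(tr) > 0) periods[i, j] <- period_autocorr(tr, dt, prominence)
  }
  # amplitude window for non-oscillating boxes: the movie-wide median
  # period, so sparse flashes are windowed like waves, not whole-record
  ref_window <- stats::median(periods, na.rm = TRUE)
  rows <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    tr <- bs$J[i, j, ]
    if (stats::sd(tr) == 0) next
    period <- periods[i, j]
    width <- temporal_width(tr, dt)
    win <- if (!is.na(period)) period else
      if (!is.na(ref_window)) ref_window else NULL
    amp <- if (min(tr) > 0 || amplitude_normalize == "none")
      relative_amplitude(tr, dt, window_s = win,
                         normalize = amplitude_normalize)
    else NA_real_
    shift <- if (!is.null(bs_b) && stats::sd(bs_b$J[i, j, ]) > 0)
      xcorr_shift(tr, bs_b$J[i, j, ], dt) else NA_real_
    rows[[length(rows) + 1]] <-
      data.frame(i = i, j = j, period_s = period, width_s = width,
                 rel_amplitude = amp, shift_s = shift)
  }
  per_box <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), period_s = numeric(),
               width_s = numeric(), rel_amplitude = numeric(),
               shift_s = numeric())
  agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE),
                       n = sum(!is.na(x)))
  summary <- list(period_s = agg(per_box$period_s),
                  width_s = agg(per_box$width_s),
                  rel_amplitude = agg(per_box$rel_amplitude),
                  shift_s = agg(per_box$shift_s),
                  n_boxes_used = nrow(per_box),
                  box_px = box_px, dt = dt)
  structure(list(per_box = per_box, summary = summary),
            class = "cw_metrics")
}

#' @export
print.cw_metrics <- function(x, ...) {
  s <- x$summary
  cat("<cw_metrics> over", s$n_boxes_used, "boxes (box_px =", s$box_px,
      ")\n")
  for (nm in c("period_s", "width_s", "rel_amplitude", "shift_s"))
    cat(sprintf("  %-14s mean %8.3f  sd %8.3f  (n=%d)\n", nm, s[[nm]]["mean"],
                s[[nm]]["sd"], as.integer(s[[nm]]["n"])))
  invisible(x)
}
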
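#' Reconstruct the oscillation phase of a wave movie
#'
#' Per-pixel phase via the analytic-signal (Hilbert) angle of the
#' mean-removed trace, lightly band-passed around the dominant frequency
#' (pooled spectral peak): frequencies outside `band` times the dominant
#' frequency are removed before the analytic signal is formed.  Pixels
#' whose oscillation range is below `mask_frac` of the movie's median range
#' are masked invalid (phase is meaningless on quiescent cortex).
#'
#' @param movie a [cw_movie()] spanning at least 3 oscillation cycles.
#' @param band band-pass limits as multiples of the dominant frequency.
#' @param mask_frac amplitude mask threshold (fraction of median range).
#' @return An object of class `cw_phase_movie`: list with `theta` (array of
#'   wrapped phase in `(-pi, pi]`, masked pixels `NA`), `mask` (logical
#'   `ny x nx`), `dominant_period_s`, `dt`, `dx`.
#' @export
reconstruct_phase <- function(movie, band = c(0.5, 2), mask_frac = 0.1) {
  stopifnot(inherits(movie, "cw_movie"))
  d <- dim(movie$data)
  nt <- d[1]
  X <- matrix(movie$data, nt, d[2] * d[3])   # (time, pixel)
  X <- sweep(X, 2, colMeans(X))
  # dominant frequency from the pooled power spectrum
  Fx <- stats::mvfft(X)
  pow <- rowSums(Mod(Fx)^2)
  half <- 2:(floor(nt / 2) + 1)              # positive frequencies
  kdom <- half[which.max(pow[half])] - 1     # cycles per record
  T_dom <- nt * movie$dt / kdom
  if (nt * movie$dt < 3 * T_dom)
    stop("record shorter than 3 estimated oscillation periods (T ~ ",
         signif(T_dom, 3), " s)")
  # band-pass around the dominant frequency, then analytic-signal weights
  k <- c(0:(nt %/% 2), -((nt - nt %/% 2 - 1):1))   # signed cycles/record
  keep <- abs(k) >= band[1] * kdom & abs(k) <= band[2] * kdom
  h <- numeric(nt)                                  # Hilbert weights
  h[k > 0] <- 2
  h[k == 0] <- 1
  if (nt %% 2 == 0) h[nt / 2 + 1] <- 1
  wt <- h * keep
  analytic <- stats::mvfft(Fx * wt, inverse = TRUE) / nt
  theta <- atan2(Im(analytic), Re(analytic))
  theta[theta <= -pi] <- pi
  rng <- apply(matrix(movie$data, nt, d[2] * d[3]), 2,
               function(x) diff(range(x)))
  mask <- matrix(rng >= mask_frac * stats::median(rng), d[2], d[3])
  theta[, !mask] <- NA_real_
  dim(theta) <- d
  structure(list(theta = theta, mask = mask,
                 dominant_period_s = T_dom, dt = movie$dt, dx = movie$dx),
            class = "cw_phase_movie")
}

wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# winding number of every 2x2 plaquette of a wrapped phase frame.
# Convention: loop traversed (i,j) -> (i,j+1) -> (i+1,j+1) -> (i+1,j),
# positive winding = phase increasing along that loop, in array
# coordinates with y (row index) increasing downward.
plaquette_winding <- function(theta, periodic = FALSE) {
  ny <- nrow(theta); nx <- ncol(theta)
  ri <- if (periodic) seq_len(ny) else seq_len(ny - 1)
  rj <- if (periodic) seq_len(nx) else seq_len(nx - 1)
  ip <- if (periodic) c(seq_len(ny)[-1], 1) else seq_len(ny)[-1]
  jp <- if (periodic) c(seq_len(nx)[-1], 1) else seq_len(nx)[-1]
  a <- theta[ri, rj, drop = FALSE]          # (i, j)
  b <- theta[ri, jp, drop = FALSE]          # (i, j+1)
  cc <- theta[ip, jp, drop = FALSE]         # (i+1, j+1)
  d <- theta[ip, rj, drop = FALSE]          # (i+1, j)
  w <- wrap_phase(b - a) + wrap_phase(cc - b) + wrap_phase(d - cc) +
    wrap_phase(a - d)
  round(w / (2 * pi))
}

#' Detect topological phase defects in a single phase frame
#'
#' Computes the winding number (wrapped phase differences summed around
#' each 2x2 plaquette, divided by 2 pi) everywhere and reports plaquettes
#' with winding +/-1 -- the cores of spiral waves.  Positive charge means
#' phase increasing along the counterclockwise loop in array coordinates
#' (row index downward); on a mirrored display this appears clockwise.
#'
#' @param phase_frame matrix of wrapped phase (`NA` = masked).
#' @param periodic include the wraparound plaquettes of the torus.
#' @return Data frame with `x`, `y` (plaquette centers, px), `charge`.
#' @export
detect_defects <- function(phase_frame, periodic = FALSE) {
  w <- plaquette_winding(phase_frame, periodic)
  idx <- which(!is.na(w) & w != 0, arr.ind = TRUE)
  data.frame(x = idx[, 2] + 0.5, y = idx[, 1] + 0.5,
             charge = w[idx])
}

#' Net topological charge of a phase frame
#'
#' Sum of all plaquette windings.  On a fully periodic (torus) frame the
#' sum is identically zero; analysed without wraparound it equals the total
#' winding enclosed by the frame boundary.
#'
#' @param phase_frame matrix of wrapped phase.
#' @param periodic include wraparound plaquettes (default `TRUE`).
#' @return Integer net charge.
#' @export
net_charge <- function(phase_frame, periodic = TRUE) {
  w <- plaquette_winding(phase_frame, periodic)
  sum(w, na.rm = TRUE)
}

#' Track phase defects through time and log pair events
#'
#' Links defects of equal charge between consecutive frames by greedy
#' nearest-neighbour assignment within `max_step`; track appearances and
#' disappearances are then resolved into opposite-charge pair events
#' (creation/annihilation) when the two ends lie within `pair_radius` of
#' each other in the same frame, otherwise flagged unpaired.
#'
#' @param defects_by_frame list of [detect_defects()] data frames, one per
#'   frame.
#' @param max_step largest allowed per-frame displacement (px).
#' @param pair_radius largest separation of a creating/annihilating pair
#'   (px).
#' @return An object of class `cw_defect_log`: list with `tracks` (data
#'   frame: `track`, `frame`, `x`, `y`, `charge`) and `events` (data frame:
#'   `type` = creation/annihilation, `frame`, `track_pos`, `track_neg`,
#'   `separation_px`) plus `unpaired` (data frame of unmatched ends).
#' @export
track_defects <- function(defects_by_frame, max_step = 5, pair_radius = 10) {
  nf <- length(defects_by_frame)
  tracks <- list()     # each: list(id, frames, xs, ys, charge)
  active <- integer(0) # indices into tracks active in previous frame
  next_id <- 1L
  for (fr in seq_len(nf)) {
    df <- defects_by_frame[[fr]]
    if (is.null(df) || !nrow(df)) { active <- integer(0); next }
    assigned <- rep(FALSE, nrow(df))
    still <- integer(0)
    if (length(active)) {
      # greedy nearest-neighbour, same charge, distance <= max_step
      cand <- do.call(rbind, lapply(active, function(ti) {
        tr <- tracks[[ti]]
        px <- tr$xs[length(tr$xs)]; py <- tr$ys[length(tr$ys)]
        ok <- which(df$charge == tr$charge & !assigned)
        if (!length(ok)) return(NULL)
        data.frame(ti = ti, di = ok,
                   d = sqrt((df$x[ok] - px)^2 + (df$y[ok] - py)^2))
      }))
      if (!is.null(cand)) {
        cand <- cand[cand$d <= max_step, , drop = FALSE]
        cand <- cand[order(cand$d), , drop = FALSE]
        used_t <- integer(0)
        for (r in seq_len(nrow(cand))) {
          ti <- cand$ti[r]; di <- cand$di[r]
          if (ti %in% used_t || assigned[di]) next
          tr <- tracks[[ti]]
          tr$frames <- c(tr$frames, fr)
          tr$xs <- c(tr$xs, df$x[di]); tr$ys <- c(tr$ys, df$y[di])
          tracks[[ti]] <- tr
          assigned[di] <- TRUE
          used_t <- c(used_t, ti)
          still <- c(still, ti)
        }
      }
    }
    for (di in which(!assigned)) {
      tracks[[next_id]] <- list(id = next_id, frames = fr, xs = df$x[di],
                                ys = df$y[di], charge = df$charge[di])
      still <- c(still, next_id)
      next_id <- next_id + 1L
    }
    active <- still
  }
  track_df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track = tr$id, frame = tr$frames, x = tr$xs, y = tr$ys,
               charge = tr$charge)))
  # pair events: births and deaths matched within a frame
  ends <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track = tr$id, charge = tr$charge,
               birth = tr$frames[1], death = tr$frames[length(tr$frames)],
               bx = tr$xs[1], by = tr$ys[1],
               dx_ = tr$xs[length(tr$xs)], dy_ = tr$ys[length(tr$ys)])))
  pair_up <- function(frame_col, xcol, ycol, type) {
    evs <- NULL; un <- NULL
    for (fr in unique(ends[[frame_col]])) {
      if (type == "creation" && fr == 1) next        # present from start
      sel <- ends[ends[[frame_col]] == fr, , drop = FALSE]
      if (type == "annihilation" && fr == max(ends$death)) next
      pos <- sel[sel$charge > 0, , drop = FALSE]
      neg <- sel[sel$charge < 0, , drop = FALSE]
      while (nrow(pos) && nrow(neg)) {
        dmat <- outer(seq_len(nrow(pos)), seq_len(nrow(neg)),
                      Vectorize(function(i, j)
                        sqrt((pos[[xcol]][i] - neg[[xcol]][j])^2 +
                             (pos[[ycol]][i] - neg[[ycol]][j])^2)))
        mn <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        if (dmat[mn[1], mn[2]] > pair_radius) break
        evs <- rbind(evs, data.frame(
          type = type, frame = fr, track_pos = pos$track[mn[1]],
          track_neg = neg$track[mn[2]],
          separation_px = dmat[mn[1], mn[2]]))
        pos <- pos[-mn[1], , drop = FALSE]
        neg <- neg[-mn[2], , drop = FALSE]
      }
      if (nrow(pos) || nrow(neg))
        un <- rbind(un, data.frame(type = type, frame = fr,
                                   track = c(pos$track, neg$track),
                                   charge = c(pos$charge, neg$charge)))
    }
    list(evs = evs, un = un)
  }
  cr <- pair_up("birth", "bx", "by", "creation")
  an <- pair_up("death", "dx_", "dy_", "annihilation")
  structure(list(tracks = track_df,
                 events = rbind(cr$evs, an$evs),
                 unpaired = rbind(cr$un, an$un)),
            class = "cw_defect_log")
}

#' @export
print.cw_defect_log <- function(x, ...) {
  cat("<cw_defect_log>", length(unique(x$tracks$track)), "tracks,",
      if (is.null(x$events)) 0 else nrow(x$events), "pair events\n")
  invisible(x)
}
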
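# Minimal self-contained baseline TIFF support (uncompressed, grayscale,
# multi-page; 8/16-bit unsigned or 32-bit float, little-endian).  No R TIFF
# package is assumed; the subset below covers what microscopy movies need
# and nothing else.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

#' Write a movie as a multi-page grayscale TIFF
#'
#' Uncompressed little-endian baseline TIFF, one page per frame.  `dt` and
#' `dx` are embedded in the ImageDescription tag
#' (`cortexwave dt=<s> dx=<um> channel=<label>`) so [read_movie()] can
#' round-trip the calibration without sidecar files.
#'
#' @param movie a [cw_movie()].
#' @param path destination path.
#' @param type `"float64"` (default; exact round trip of double data),
#'   `"float32"`, `"uint16"` or `"uint8"` (integer movies are written
#'   as-is and must fit the range).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path,
                        type = c("float64", "float32", "uint16", "uint8")) {
  stopifnot(inherits(movie, "cw_movie"))
  type <- match.arg(type)
  d <- dim(movie$data)
  nt <- d[1]; ny <- d[2]; nx <- d[3]
  bits <- switch(type, float64 = 64L, float32 = 32L, uint16 = 16L,
                 uint8 = 8L)
  fmt  <- switch(type, float64 = 3L, float32 = 3L, 1L)
  if (!startsWith(type, "float")) {
    rng <- range(movie$data)
    if (rng[1] < 0 || rng[2] > 2^bits - 1 || any(movie$data %% 1 != 0))
      stop("movie values do not fit ", type, " losslessly; use float32")
  }
  desc <- sprintf("cortexwave dt=%.17g dx=%.17g channel=%s",
                  movie$dt, movie$dx, movie$channel)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  bytes_px <- bits / 8L
  strip_len <- nx * ny * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)  # little-endian magic
  # layout: header(8) | desc | frame strips | IFDs
  desc_off <- 8L
  data0 <- desc_off + length(desc_raw)
  ifd0 <- data0 + nt * strip_len
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  for (k in seq_len(nt)) {
    fr <- t(movie$data[k, , ])            # row-major pixel order
    if (startsWith(type, "float"))
      writeBin(as.numeric(fr), con, size = bytes_px, endian = "little")
    else if (type == "uint16")
      writeBin(as.integer(fr), con, size = 2, endian = "little")
    else writeBin(as.raw(as.integer(fr)), con)
  }
  entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (k in seq_len(nt)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 3, 1, nx)
    entry(257, 3, 1, ny)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)                    # no compression
    entry(262, 3, 1, 1)                    # BlackIsZero
    entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, data0 + (k - 1L) * strip_len)
    entry(277, 3, 1, 1)
    entry(278, 3, 1, ny)
    entry(279, 4, 1, strip_len)
    entry(339, 3, 1, fmt)
    next_off <- if (k < nt) ifd0 + k * ifd_size else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tiff_raw <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  rd <- function(off, size, n = 1, what = "integer", signed = TRUE)
    readBin(raw_all[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  magic <- rawToChar(raw_all[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  frames <- list(); desc <- NULL
  ifd_off <- rd(4, 4)
  while (ifd_off > 0) {
    n <- rd(ifd_off, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rd(base, 2, signed = FALSE)
      typ <- rd(base + 2, 2, signed = FALSE)
      cnt <- rd(base + 4, 4)
      tsz <- c(1, 1, 2, 4, 8)[typ]
      val <- if (tsz * cnt <= 4) {
        if (typ == 3) rd(base + 8, 2, n = cnt, signed = FALSE)
        else if (typ %in% c(1, 2)) rd(base + 8, 1, n = cnt, signed = FALSE)
        else rd(base + 8, 4, n = cnt)
      } else {
        off <- rd(base + 8, 4)
        if (typ == 3) rd(off, 2, n = cnt, signed = FALSE)
        else if (typ == 2) off + 0   # string: store offset, handle below
        else rd(off, 4, n = cnt)
      }
      if (typ == 2) {   # ASCII
        off <- if (cnt <= 4) base + 8 else rd(base + 8, 4)
        val <- rawToChar(raw_all[(off + 1):(off + cnt - 1)])
      }
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing required TIFF tag ", tag)
        default
      } else v
    }
    if (need(259, 1) != 1) stop("compressed TIFF not supported")
    nx <- need(256); ny <- need(257)
    bits <- need(258, 8); fmt <- need(339, 1)
    if (need(277, 1) != 1) stop("multi-sample TIFF not supported")
    offs <- need(273); cnts <- need(279)
    if (is.null(desc)) desc <- tags[["270"]]
    px <- numeric(0)
    for (sidx in seq_along(offs)) {
      npx <- cnts[sidx] / (bits / 8)
      px <- c(px, if (fmt == 3)
        rd(offs[sidx], bits / 8, n = npx, what = "numeric")
        else rd(offs[sidx], bits / 8, n = npx, signed = FALSE))
    }
    if (length(px) != nx * ny) stop("non-uniform or truncated TIFF strips")
    frames[[length(frames) + 1]] <- matrix(px, ny, nx, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2 + n * 12, 4)
  }
  list(frames = frames, description = desc)
}

#' Read a multi-frame grayscale TIFF as a movie
#'
#' Supports uncompressed baseline TIFF, 8/16-bit unsigned or 32-bit float,
#' either endianness.  Integer intensities are converted to double without
#' rescaling.  Frame calibration comes from explicit `dt`/`dx` arguments,
#' falling back to a `cortexwave dt=... dx=...` ImageDescription when
#' present.
#'
#' @param path TIFF path.
#' @param dt,dx frame interval (s) and pixel size (um); `NULL` to use
#'   embedded metadata.
#' @param channel optional channel label override.
#' @return A [cw_movie()].
#' @export
read_movie <- function(path, dt = NULL, dx = NULL, channel = NULL) {
  tf <- read_tiff_raw(path)
  if (!length(tf$frames)) stop("no frames in ", path)
  shp <- dim(tf$frames[[1]])
  for (fr in tf$frames)
    if (!identical(dim(fr), shp)) stop("non-uniform frame shapes in ", path)
  meta <- list(dt = NA_real_, dx = NA_real_, channel = "intensity")
  if (!is.null(tf$description) &&
      grepl("^cortexwave ", tf$description)) {
    kv <- strsplit(sub("^cortexwave ", "", tf$description), " ")[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=")[[1]]
      if (parts[1] %in% c("dt", "dx"))
        meta[[parts[1]]] <- as.numeric(parts[2])
      if (parts[1] == "channel") meta$channel <- parts[2]
    }
  }
  dt <- if (is.null(dt)) meta$dt else dt
  dx <- if (is.null(dx)) meta$dx else dx
  if (is.na(dt) || is.na(dx))
    stop("dt and dx must be given (no embedded calibration found)")
  arr <- array(0, c(length(tf$frames), shp[1], shp[2]))
  for (k in seq_along(tf$frames)) arr[k, , ] <- tf$frames[[k]]
  cw_movie(arr, dt, dx,
           if (is.null(channel)) meta$channel else channel)
}
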
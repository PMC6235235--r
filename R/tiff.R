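# Minimal baseline TIFF support (no image package is assumed).
#
# Writer: little-endian, uncompressed, grayscale, one strip per page;
# uint8 / uint16 / float32. Voxel spacing is recorded the ImageJ way:
# XResolution / YResolution hold pixels-per-micron as rationals and the
# first page's ImageDescription carries "unit=micron" and "spacing=<dz>".
# Reader: handles that subset (either byte order, multiple strips),
# which covers files from this package and from tifffile/ImageJ with
# default settings; anything compressed or tiled raises a format error.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, XResolution = 282L, YResolution = 283L,
               ResolutionUnit = 296L, SampleFormat = 339L)

#' Write a stack as a multi-page TIFF
#'
#' @param grid a [voxel_grid()]; each z-slice becomes one page.
#' @param path destination file (written atomically).
#' @param dtype `"auto"` (uint8/uint16 when the data are non-negative
#'   integers in range, else float32), or one of `"uint8"`, `"uint16"`,
#'   `"float32"`.
#' @param metadata write spacing metadata (resolution tags + ImageJ
#'   description)? `FALSE` produces a bare TIFF, e.g. to exercise the
#'   missing-spacing error path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, dtype = c("auto", "uint8", "uint16", "float32"),
                        metadata = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  dtype <- match.arg(dtype)
  a <- grid$data
  if (dtype == "auto") {
    intlike <- all(a >= 0) && all(a == round(a))
    dtype <- if (intlike && max(a) <= 255) "uint8"
             else if (intlike && max(a) <= 65535) "uint16"
             else "float32"
  }
  if (dtype %in% c("uint8", "uint16")) {
    lim <- if (dtype == "uint8") 255 else 65535
    if (any(a < 0) || any(a > lim) || any(a != round(a)))
      stop("data do not fit dtype ", dtype)
  }
  atomic_write(path, function(tmp) write_tiff_impl(grid, tmp, dtype, metadata))
}

write_tiff_impl <- function(grid, path, dtype, metadata = TRUE) {
  d <- dim(grid$data)                        # (nz, ny, nx)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  sp <- grid$spacing                         # (dz, dy, dx)
  bps <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- switch(dtype, uint8 = 1L, uint16 = 1L, float32 = 3L)
  bytes_px <- bps %/% 8L
  strip_len <- nx * ny * bytes_px
  desc <- sprintf("ImageJ=1.53\nimages=%d\nslices=%d\nunit=micron\nspacing=%.9g\n",
                  nz, nz, sp[1])
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  # rationals: pixels per micron = 1/dx (x), 1/dy (y)
  rat <- function(pitch) c(10000000L, as.integer(round(pitch * 1e7)))
  n_tags <- if (metadata) length(TIFF_TAGS) else length(TIFF_TAGS) - 4L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout per page: [IFD][xres rational 8][yres rational 8][desc?][strip]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42L)
  w4(8L)                                     # first IFD right after header
  offset <- 8L
  for (s in seq_len(nz)) {
    first <- s == 1L && metadata
    extra <- if (metadata) 16L + if (first) length(desc_raw) else 0L else 0L
    data_off <- offset + ifd_size + extra
    next_ifd <- if (s < nz) data_off + strip_len else 0L
    w2(n_tags)
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    res_off <- offset + ifd_size
    desc_off <- res_off + 16L
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    entry(258L, 3L, 1L, bps)
    entry(259L, 3L, 1L, 1L)                  # no compression
    entry(262L, 3L, 1L, 1L)                  # black is zero
    if (metadata) {
      if (first) entry(270L, 2L, length(desc_raw), desc_off)
      else entry(270L, 2L, 1L, 0L)           # empty description
    }
    entry(273L, 4L, 1L, data_off)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, strip_len)
    if (metadata) {
      entry(282L, 5L, 1L, res_off)
      entry(283L, 5L, 1L, res_off + 8L)
      entry(296L, 3L, 1L, 1L)                # unit: none (ImageJ convention)
    }
    entry(339L, 3L, 1L, fmt)
    w4(next_ifd)
    if (metadata) {
      w4(rat(sp[3]))                         # XResolution = 1e7 / (dx*1e7)
      w4(rat(sp[2]))
      if (first) writeBin(desc_raw, con)
    }
    slice <- t(grid$data[s, , ])             # row-major: y rows, x cols
    vals <- as.vector(slice)                 # x fastest
    if (dtype == "float32") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else if (dtype == "uint16") {
      v <- as.integer(vals)
      v[v > 32767L] <- v[v > 32767L] - 65536L   # reinterpret as signed
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.raw(vals), con)
    }
    offset <- data_off + strip_len
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file (uncompressed grayscale, uint8/uint16/float32).
#' @param spacing optional `(dz, dy, dx)` um override. Without it the
#'   spacing must be recoverable from the file's resolution tags and
#'   ImageJ-style `spacing=` description; if neither is present an error
#'   is raised — spacing is never silently defaulted.
#' @return a [voxel_grid()].
#' @export
read_stack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated header): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  getint <- function(off, size, signed = FALSE) {
    v <- readBin(raw[(off + 1):(off + size)], "integer", size = size,
                 endian = endian, signed = signed || size == 4)
    if (!signed && size == 4 && v < 0) v <- v + 2^32
    if (!signed && size == 2 && v < 0) v <- v + 65536
    v
  }
  if (getint(2, 2) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- getint(4, 4)
  slices <- list()
  meta <- list(dx = NA_real_, dy = NA_real_, dz = NA_real_)
  while (ifd_off != 0L) {
    if (ifd_off + 2 > length(raw)) stop("truncated TIFF: IFD out of range")
    n <- getint(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- getint(e, 2); type <- getint(e + 2, 2); count <- getint(e + 4, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, off = e + 8)
    }
    val <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      sz <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[t$type]
      total <- sz * t$count
      off <- if (total <= 4L) t$off else getint(t$off, 4)
      if (t$type == 3L) vapply(seq_len(t$count) - 1L,
                               function(k) getint(off + 2 * k, 2), 1)
      else if (t$type %in% c(4L, 1L))
        vapply(seq_len(t$count) - 1L, function(k) getint(off + sz * k, sz), 1)
      else if (t$type == 5L)
        vapply(seq_len(t$count) - 1L, function(k)
          getint(off + 8 * k, 4) / getint(off + 8 * k + 4, 4), 1)
      else if (t$type == 2L) {
        chars <- raw[(off + 1):(off + t$count)]
        rawToChar(chars[chars != as.raw(0)])
      } else stop("unsupported TIFF tag type ", t$type)
    }
    comp <- val(259, 1L)
    if (comp != 1L) stop("unsupported TIFF: compressed data (compression ",
                         comp, ")")
    if (val(277, 1L) != 1L) stop("unsupported TIFF: multiple samples per pixel")
    nx <- val(256); ny <- val(257); bps <- val(258); fmt <- val(339, 1L)
    offs <- val(273); counts <- val(279)
    rps <- val(278, ny)
    if (is.null(nx) || is.null(ny) || is.null(offs))
      stop("malformed TIFF: missing required tags")
    xr <- val(282); yr <- val(283)
    if (!is.null(xr) && xr > 0) meta$dx <- 1 / xr
    if (!is.null(yr) && yr > 0) meta$dy <- 1 / yr
    dsc <- val(270)
    if (!is.null(dsc) && grepl("spacing=", dsc)) {
      m <- regmatches(dsc, regexec("spacing=([0-9.eE+-]+)", dsc))[[1]][2]
      meta$dz <- as.numeric(m)
    }
    bytes_px <- bps %/% 8L
    buf <- raw(0)
    for (k in seq_along(offs)) {
      o <- offs[k]; cnt <- counts[k]
      if (o + cnt > length(raw)) stop("truncated TIFF: strip out of range")
      buf <- c(buf, raw[(o + 1):(o + cnt)])
    }
    npx <- nx * ny
    vals <- if (fmt == 3L && bps == 32L) {
      readBin(buf, "numeric", n = npx, size = 4, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bps == 16L) {
      v <- readBin(buf, "integer", n = npx, size = 2, endian = endian,
                   signed = FALSE)
      as.numeric(v)
    } else if (fmt %in% c(1L, 4L) && bps == 8L) {
      as.numeric(as.integer(buf[seq_len(npx)]))
    } else stop("unsupported TIFF pixel format (bits ", bps, ", format ",
                fmt, ")")
    slices[[length(slices) + 1L]] <- t(matrix(vals, nx, ny))  # (ny, nx)
    ifd_off <- getint(ifd_off + 2 + n * 12, 4)
  }
  if (!length(slices)) stop("TIFF contains no images")
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  if (!all(vapply(slices, function(s) all(dim(s) == c(ny, nx)), TRUE)))
    stop("TIFF pages have inconsistent dimensions")
  arr <- array(0, c(length(slices), ny, nx))
  for (s in seq_along(slices)) arr[s, , ] <- slices[[s]]
  if (is.null(spacing)) {
    spacing <- c(meta$dz, meta$dy, meta$dx)
    if (any(is.na(spacing)))
      stop("no voxel spacing in TIFF metadata and no 'spacing' override given")
  }
  voxel_grid(arr, spacing)
}
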
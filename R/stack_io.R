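# Shared data model and image/table I/O.
#
# Conventions used everywhere in this package:
#   * arrays are 3D with dim = (z, y, x); index grid$data[z, y, x]
#   * all physical quantities are micrometres; spacing = (dz, dy, dx)
#   * voxel centres sit at (index - 1) * spacing (0-based physically,
#     1-based as R indices)

#' Construct a voxel grid
#'
#' A `voxel_grid` is a 3D scalar fluorescence volume with physical voxel
#' spacing attached. Axis order is fixed to (z, y, x).
#'
#' @param data 3D numeric array of nonnegative intensities, dim (z, y, x).
#' @param spacing numeric length-3, voxel spacing (dz, dy, dx) in micrometres;
#'   all strictly positive.
#' @param channel channel name, e.g. `"dapi"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, channel = "dapi") {
  if (length(dim(data)) != 3L)
    stop("voxel_grid data must have exactly 3 axes (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (dz, dy, dx)")
  structure(list(data = data, spacing = spacing, channel = as.character(channel)),
            class = "voxel_grid")
}

#' Construct a label volume
#'
#' Integer segmentation labels sharing a grid's geometry; 0 is background.
#'
#' @param labels 3D integer array, dim (z, y, x), values >= 0.
#' @param spacing voxel spacing (dz, dy, dx) in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing) {
  if (length(dim(labels)) != 3L)
    stop("label_volume labels must have exactly 3 axes (z, y, x)")
  if (!is.integer(labels)) {
    storage.mode(labels) <- "integer"
  }
  if (anyNA(labels) || min(labels) < 0L)
    stop("labels must be nonnegative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (dz, dy, dx)")
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> channel '%s'  %d x %d x %d (z,y,x)  spacing %.4f/%.4f/%.4f um\n",
              x$channel, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d labels  %d x %d x %d (z,y,x)  spacing %.4f/%.4f/%.4f um\n",
              max(x$labels), d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

stopifnot_same_geometry <- function(a_dim, a_spacing, b_dim, b_spacing, what) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s: array shapes differ (%s vs %s)", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  if (max(abs(a_spacing - b_spacing)) > 1e-9)
    stop(sprintf("%s: voxel spacings differ", what))
  invisible(TRUE)
}

# ---- TIFF I/O --------------------------------------------------------------

# Spacing metadata dialects understood by read_stack():
#  * OME-XML in the ImageDescription tag (PhysicalSizeX/Y/Z attributes)
#  * ImageJ-style description ("spacing=<dz>", "unit=micron") together with
#    the TIFF X/Y resolution tags (pixels per unit)
# write_stack() emits the ImageJ dialect, which readers of both kinds accept.

parse_tiff_spacing <- function(info) {
  desc <- attr(info, "description")
  dz <- dy <- dx <- NA_real_
  if (!is.null(desc) && nzchar(desc)) {
    if (grepl("<OME", desc, fixed = TRUE) || grepl("PhysicalSize", desc, fixed = TRUE)) {
      gx <- regmatches(desc, regexec('PhysicalSizeX="([0-9.eE+-]+)"', desc))[[1]]
      gy <- regmatches(desc, regexec('PhysicalSizeY="([0-9.eE+-]+)"', desc))[[1]]
      gz <- regmatches(desc, regexec('PhysicalSizeZ="([0-9.eE+-]+)"', desc))[[1]]
      if (length(gx) == 2) dx <- as.numeric(gx[2])
      if (length(gy) == 2) dy <- as.numeric(gy[2])
      if (length(gz) == 2) dz <- as.numeric(gz[2])
    } else if (grepl("spacing=", desc, fixed = TRUE)) {
      gz <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
      if (length(gz) == 2) dz <- as.numeric(gz[2])
    }
  }
  if (is.na(dx)) {
    xres <- attr(info, "x.resolution")
    yres <- attr(info, "y.resolution")
    if (!is.null(xres) && is.finite(xres) && xres > 0) dx <- 1 / xres
    if (!is.null(yres) && is.finite(yres) && yres > 0) dy <- 1 / yres
  }
  if (is.na(dy)) dy <- dx
  c(dz, dy, dx)
}

#' Read a TIFF / OME-TIFF z-stack
#'
#' Reads a multi-page TIFF as a `voxel_grid` with (z, y, x) axis order.
#' Voxel spacing is taken from OME-XML `PhysicalSize*` attributes or
#' ImageJ-style tags; a `spacing` argument always overrides file metadata.
#'
#' @param path path to a TIFF file.
#' @param channel channel name to attach to the grid.
#' @param spacing optional (dz, dy, dx) in micrometres, overriding metadata.
#' @return A [voxel_grid].
#' @export
read_stack <- function(path, channel = "dapi", spacing = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L && is.null(spacing))
    stop("2D-only image: a z-stack needs at least 2 optical sections (or pass spacing explicitly)")
  meta <- parse_tiff_spacing(pages[[1]])
  if (is.null(spacing)) {
    if (anyNA(meta))
      stop("no voxel spacing found in TIFF metadata; supply `spacing = c(dz, dy, dx)`")
    spacing <- meta
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  voxel_grid(arr, spacing, channel)
}

imagej_description <- function(nz, dz) {
  sprintf("ImageJ=1.53t\nimages=%d\nslices=%d\nunit=micron\nspacing=%.6f\nloop=false\n",
          nz, nz, dz)
}

#' Write a voxel grid to TIFF
#'
#' Intensities are written as 16-bit unsigned integers (values are rounded
#' and clipped to 0..65535) in a plain baseline multi-page TIFF with
#' ImageJ-style spacing metadata (description tag plus X/Y resolution)
#' that [read_stack()] and mainstream viewers round-trip.
#'
#' @param grid a [voxel_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  vals <- pmin(pmax(round(grid$data), 0), 65535)
  desc <- imagej_description(d[1], grid$spacing[1])
  write_tiff16(vals, path, desc, xres = 1 / grid$spacing[3],
               yres = 1 / grid$spacing[2])
  invisible(path)
}

# Minimal baseline TIFF writer: multi-page, uncompressed, 16-bit grayscale,
# little-endian, with ImageDescription and X/Y resolution tags on the first
# page. (The installed tiff package reads arbitrary TIFFs but cannot write
# metadata tags, which the spacing round-trip requires.)
write_tiff16 <- function(vals, path, description, xres, yres) {
  d <- dim(vals)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  npix <- ny * nx
  desc_raw <- c(charToRaw(description), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  u16 <- function(v) { v <- as.integer(round(v)); v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = 2, endian = "little") }
  u32 <- function(v) { v <- as.numeric(v); v[v > 2^31 - 1] <- v[v > 2^31 - 1] - 2^32
    writeBin(as.integer(v), con, size = 4, endian = "little") }
  rational <- function(x) {          # x as num/denom with 1e6 denominator
    u32(round(x * 1e6)); u32(1e6)
  }
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count); value()
  }

  # layout: header | strips | description | 2 rationals | IFDs
  strip_off <- 8 + (seq_len(nz) - 1) * 2 * npix
  desc_off <- 8 + nz * 2 * npix
  xres_off <- desc_off + length(desc_raw)
  yres_off <- xres_off + 8
  ifd0 <- yres_off + 8
  ntags <- c(12L, rep(8L, max(nz - 1, 0)))    # metadata tags on page 1 only
  ifd_size <- 2 + 12 * ntags + 4
  ifd_off <- ifd0 + cumsum(c(0, ifd_size[-nz]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd0)
  for (z in seq_len(nz)) {
    page <- t(vals[z, , ])                    # row-major scanlines
    u16(as.vector(page))
  }
  writeBin(desc_raw, con)
  rational(xres); rational(yres)
  for (z in seq_len(nz)) {
    u16(ntags[z])
    entry(256, 3, 1, function() { u16(nx); u16(0L) })           # width
    entry(257, 3, 1, function() { u16(ny); u16(0L) })           # length
    entry(258, 3, 1, function() { u16(16L); u16(0L) })          # bits/sample
    entry(259, 3, 1, function() { u16(1L); u16(0L) })           # no compression
    entry(262, 3, 1, function() { u16(1L); u16(0L) })           # black is zero
    if (z == 1)
      entry(270, 2, length(desc_raw), function() u32(desc_off)) # description
    entry(273, 4, 1, function() u32(strip_off[z]))              # strip offset
    entry(278, 3, 1, function() { u16(ny); u16(0L) })           # rows/strip
    entry(279, 4, 1, function() u32(2 * npix))                  # strip bytes
    if (z == 1) {
      entry(282, 5, 1, function() u32(xres_off))                # x resolution
      entry(283, 5, 1, function() u32(yres_off))                # y resolution
      entry(296, 3, 1, function() { u16(1L); u16(0L) })         # unitless
    }
    u32(if (z < nz) ifd_off[z + 1] else 0)
  }
  invisible(path)
}

#' Read a label volume from TIFF
#'
#' @param path path to a uint16 label TIFF written by [write_labels()].
#' @param spacing optional (dz, dy, dx) override.
#' @return A [label_volume].
#' @export
read_labels <- function(path, spacing = NULL) {
  g <- read_stack(path, channel = "labels", spacing = spacing)
  lab <- g$data
  storage.mode(lab) <- "integer"
  label_volume(lab, g$spacing)
}

#' Write a label volume to TIFF (uint16)
#'
#' @param labels a [label_volume] with at most 65535 labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  if (max(labels$labels) > 65535L) stop("more than 65535 labels; uint16 TIFF cannot hold them")
  g <- voxel_grid(labels$labels + 0, labels$spacing, "labels")
  write_stack(g, path)
}

# ---- record tables ---------------------------------------------------------

#' Write per-nucleus records to CSV
#'
#' Serializes a nucleus feature table (and any attached cell-cycle calls) to
#' a plain CSV with one row per nucleus. Columns keep their documented units
#' (micrometres for lengths, cubic micrometres for volumes); factor-like
#' class columns are written as their literal string codes
#' (e.g. `"UNCLASSIFIED"`). The file reloads losslessly with
#' [read_records()].
#'
#' @param records non-empty data.frame of per-nucleus records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read per-nucleus records from CSV
#'
#' @param path CSV written by [write_records()].
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
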
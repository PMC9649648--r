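# Slide I/O: TIFF reading via the tiff package, writing via a minimal
# baseline-TIFF encoder.  The writer exists because writeTIFF() cannot emit
# XResolution/YResolution tags, and the um/px metadata must round-trip for
# load_slide() to recover the physical scale without an override.

#' Construct an in-memory slide
#'
#' @param pixels RGB raster, an `H x W x 3` array with values in `[0, 1]`.
#' @param slide_id Character identifier.
#' @param mpp Physical resolution in micrometers per pixel (> 0).
#' @return A `slide_image` object (list with `slide_id`, `pixels`, `mpp`).
#' @export
slide_image <- function(pixels, slide_id, mpp) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    stop("expected RGB: pixels must be an H x W x 3 array", call. = FALSE)
  stopifnot_scalar_in(mpp, 1e-6, Inf, "mpp")
  structure(list(slide_id = as.character(slide_id), pixels = pixels, mpp = mpp),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s: %d x %d px RGB at %.4g um/px (%.2f x %.2f mm)\n",
              x$slide_id, d[2], d[1], x$mpp,
              d[2] * x$mpp / 1000, d[1] * x$mpp / 1000))
  invisible(x)
}

#' Load a whole-slide TIFF
#'
#' Reads an 8-bit RGB TIFF/BigTIFF and recovers the physical resolution from
#' the XResolution tag (pixels per cm or inch). A `mpp` override takes
#' precedence; without either, loading is refused because all tile geometry is
#' physical.
#'
#' @param path Path to a TIFF file.
#' @param mpp Optional resolution override in um/px.
#' @param slide_id Identifier; defaults to the file name without extension.
#' @return A [slide_image()].
#' @export
load_slide <- function(path, mpp = NULL, slide_id = NULL) {
  if (!file.exists(path)) stop("slide file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, info = TRUE)
  d <- dim(img)
  if (length(d) != 3 || d[3] < 3)
    stop("expected RGB: ", path, " has ", if (length(d) == 2) 1 else d[3],
         " channel(s)", call. = FALSE)
  if (d[3] > 3) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (is.null(mpp)) {
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit") %||% "inch"
    if (is.null(xres) || !is.finite(xres) || xres <= 0)
      stop("no resolution metadata in ", path,
           " and no mpp override supplied", call. = FALSE)
    um_per_unit <- switch(unit, cm = 1e4, inch = 25400, 1e4)
    mpp <- um_per_unit / xres
  }
  attributes(img) <- list(dim = dim(img))
  slide_image(img, slide_id %||% sub("\\.[^.]*$", "", basename(path)), mpp)
}

#' Write a slide as a baseline TIFF with resolution metadata
#'
#' Emits an uncompressed 8-bit RGB baseline TIFF with XResolution/YResolution
#' recorded in pixels per centimeter, so [load_slide()] recovers `mpp`.
#'
#' @param slide A [slide_image()], or an `H x W x 3` array in `[0, 1]`
#'   (then `mpp` is required).
#' @param path Output path.
#' @param mpp Resolution in um/px when `slide` is a bare array.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, mpp = NULL) {
  if (inherits(slide, "slide_image")) {
    img <- slide$pixels; mpp <- slide$mpp
  } else {
    img <- slide
    if (is.null(mpp)) stop("mpp required when writing a bare array", call. = FALSE)
  }
  write_tiff_rgb(img, path, mpp)
  invisible(path)
}

# Minimal little-endian baseline TIFF writer: single strip, uncompressed,
# 8-bit RGB, resolution tags in px/cm.
write_tiff_rgb <- function(img, path, mpp) {
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3)
  h <- d[1]; w <- d[2]
  px <- as.raw(round(clamp(img, 0, 1) * 255))
  dim(px) <- d
  data <- as.vector(aperm(px, c(3, 2, 1)))  # RGB-interleaved, row-major
  n_data <- length(data)

  px_per_cm <- 1e4 / mpp
  res_num <- round(px_per_cm * 1000); res_den <- 1000

  off_data <- 8L
  off_bps  <- off_data + n_data
  if (off_bps %% 2 == 1) { data <- c(data, as.raw(0)); off_bps <- off_bps + 1L }
  off_xres <- off_bps + 6L
  off_yres <- off_xres + 8L
  off_ifd  <- off_yres + 8L

  con <- file(path, "wb")
  on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wb4 <- function(x) for (v in x) {
    v <- as.double(v)
    wb2(v %% 65536); wb2(v %/% 65536)
  }
  writeBin(charToRaw("II"), con); wb2(42L); wb4(off_ifd)
  writeBin(data, con)
  wb2(c(8L, 8L, 8L))            # BitsPerSample values
  wb4(c(res_num, res_den))      # XResolution rational
  wb4(c(res_num, res_den))      # YResolution rational

  entry <- function(tag, type, count, value, short = FALSE) {
    wb2(tag); wb2(type); wb4(count)
    if (short) { wb2(value); wb2(0L) } else wb4(value)
  }
  wb2(12L)  # entry count
  entry(256L, 4L, 1L, w)                  # ImageWidth
  entry(257L, 4L, 1L, h)                  # ImageLength
  entry(258L, 3L, 3L, off_bps)            # BitsPerSample
  entry(259L, 3L, 1L, 1L, short = TRUE)   # Compression: none
  entry(262L, 3L, 1L, 2L, short = TRUE)   # Photometric: RGB
  entry(273L, 4L, 1L, off_data)           # StripOffsets
  entry(277L, 3L, 1L, 3L, short = TRUE)   # SamplesPerPixel
  entry(278L, 4L, 1L, h)                  # RowsPerStrip
  entry(279L, 4L, 1L, n_data)             # StripByteCounts
  entry(282L, 5L, 1L, off_xres)           # XResolution
  entry(283L, 5L, 1L, off_yres)           # YResolution
  entry(296L, 3L, 1L, 3L, short = TRUE)   # ResolutionUnit: cm
  wb4(0L)  # next IFD
  invisible(path)
}
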
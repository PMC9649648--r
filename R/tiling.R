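# Two-scale tile grids over a slide raster.  High-resolution tiles sit on
# the native 0.44 um/px raster; the low-resolution raster is the exact
# 1:3 area-average downscale tiled with the same 299 px geometry.  Edge
# remainders are discarded (adjacent, non-overlapping, fixed-size tiles);
# coordinates are 0-based pixels with a top-left origin and half-open
# extents [x, x + tile_px).

#' Build the tile grid for one scale
#'
#' @param slide A [slide_image()] at the high (native) resolution.
#' @param scale `"high"` (0.44 um/px) or `"low"` (1.32 um/px via 1:3
#'   area-average downscaling).
#' @param tile_px Tile side, default 299.
#' @param sat_threshold Saturation threshold of the tissue detector.
#' @return A `tile_grid`: list with `slide_id`, `scale`, `tile_px`, `mpp`,
#'   raster dims at that scale, and `tiles` (data.frame row, col, x_px,
#'   y_px, tissue_fraction).  Empty (with a warning) when the slide is
#'   smaller than one tile.
#' @export
build_grid <- function(slide, scale = c("high", "low"), tile_px = .hs_geometry$tile_px,
                       sat_threshold = 0.08) {
  stopifnot(inherits(slide, "slide_image"))
  scale <- match.arg(scale)
  if (abs(slide$mpp - .hs_geometry$mpp_high) > 1e-6)
    stop("slide raster must be at the high resolution (0.44 um/px); ",
         "the low scale is derived by 1:3 downscaling", call. = FALSE)
  raster <- scale_raster(slide$pixels, scale)
  H <- dim(raster)[1]; W <- dim(raster)[2]
  nr <- H %/% tile_px; nc <- W %/% tile_px
  mpp <- if (scale == "high") .hs_geometry$mpp_high else .hs_geometry$mpp_low
  if (nr < 1 || nc < 1) {
    warning("slide smaller than one ", scale, "-scale tile; empty grid")
    tiles <- data.frame(row = integer(0), col = integer(0), x_px = integer(0),
                        y_px = integer(0), tissue_fraction = numeric(0))
  } else {
    g <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
    g <- g[order(g$row, g$col), ]
    tiles <- data.frame(row = g$row, col = g$col,
                        x_px = g$col * tile_px, y_px = g$row * tile_px)
    # one saturation pass over the raster, then per-tile means
    sat <- rgb_saturation(raster) > sat_threshold
    tiles$tissue_fraction <- vapply(seq_len(nrow(tiles)), function(i) {
      mean(sat[tiles$y_px[i] + seq_len(tile_px), tiles$x_px[i] + seq_len(tile_px)])
    }, numeric(1))
    rownames(tiles) <- NULL
  }
  structure(list(slide_id = slide$slide_id, scale = scale, tile_px = as.integer(tile_px),
                 mpp = mpp, raster_h = H, raster_w = W, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %s, %s scale (%.2f um/px): %d tiles of %d px over %d x %d px\n",
              x$slide_id, x$scale, x$mpp, nrow(x$tiles), x$tile_px, x$raster_w, x$raster_h))
  invisible(x)
}

# Raster at a grid scale: identity for high, exact 1:3 block mean for low
# (cropping the remainder so the factor divides).
scale_raster <- function(pixels, scale) {
  if (scale == "high") return(pixels)
  H <- dim(pixels)[1] - dim(pixels)[1] %% 3L
  W <- dim(pixels)[2] - dim(pixels)[2] %% 3L
  block_mean(pixels[seq_len(H), seq_len(W), , drop = FALSE], 3L)
}

#' Extract one tile from a raster
#'
#' @param raster H x W x 3 array.
#' @param row,col 0-based tile indices.
#' @param tile_px Tile side.
#' @return `tile_px x tile_px x 3` array.
#' @export
extract_tile <- function(raster, row, col, tile_px = .hs_geometry$tile_px) {
  ys <- row * tile_px + seq_len(tile_px)
  xs <- col * tile_px + seq_len(tile_px)
  if (max(ys) > dim(raster)[1] || max(xs) > dim(raster)[2])
    stop("tile extends beyond the raster", call. = FALSE)
  raster[ys, xs, , drop = FALSE]
}

#' Tissue fraction of a tile
#'
#' Fraction of pixels whose HSV saturation exceeds the threshold; blank
#' glass and pure-white vacoule regions are unsaturated.  Tiles below
#' `min_tissue` (default 0.05) are treated as background upstream.
#'
#' @param tile RGB array.
#' @param sat_threshold Saturation threshold, default 0.08.
#' @return Fraction in `[0, 1]`.
#' @export
tissue_fraction <- function(tile, sat_threshold = 0.08) {
  mean(rgb_saturation(tile) > sat_threshold)
}

#' Serialize a tile grid to CSV
#' @param grid A `tile_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  df <- cbind(slide_id = grid$slide_id, scale = grid$scale, grid$tiles)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
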
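# Spatial histological feature maps: per-tile class probabilities over a
# slide's grid, with background tiles short-circuited into the ignore mask.

#' Apply a classifier across a slide's tile grid
#'
#' Classifies every tissue tile of the grid; tiles whose tissue fraction is
#' below `min_tissue` are marked ignore without inference.  Deterministic
#' for a fixed model and independent of tile processing order.
#'
#' @param model A trained `tile_cnn` (or any object with a
#'   [classify_tiles()] method whose spec matches the grid scale).
#' @param slide The [slide_image()] the grid was built on.
#' @param grid A `tile_grid` of the model's scale.
#' @param min_tissue Background threshold on the tile tissue fraction.
#' @return A `feature_map`: grid-shaped per-tile probability vectors,
#'   argmax classes and ignore mask.
#' @export
map_slide <- function(model, slide, grid, min_tissue = .hs_geometry$min_tissue) {
  stopifnot(inherits(grid, "tile_grid"), inherits(slide, "slide_image"))
  spec <- model$spec
  if (!is.null(spec$scale) && !identical(spec$scale, grid$scale))
    stop("scale mismatch: model expects ", spec$scale, " tiles, grid is ",
         grid$scale, call. = FALSE)
  raster <- scale_raster(slide$pixels, grid$scale)
  nt <- nrow(grid$tiles)
  K <- spec$n_classes
  probs <- matrix(NA_real_, nt, K, dimnames = list(NULL, spec$labels))
  use <- which(grid$tiles$tissue_fraction >= min_tissue)
  if (length(use)) {
    tiles <- lapply(use, function(i)
      extract_tile(raster, grid$tiles$row[i], grid$tiles$col[i], grid$tile_px))
    probs[use, ] <- classify_tiles(model, tiles)
  }
  argmax <- rep(NA_integer_, nt)
  argmax[use] <- max.col(probs[use, , drop = FALSE])
  ignore <- is.na(argmax) | argmax == K
  structure(list(slide_id = grid$slide_id, feature = spec$feature,
                 rows = max(grid$tiles$row) + 1L, cols = max(grid$tiles$col) + 1L,
                 tiles = grid$tiles[, c("row", "col")],
                 probs = probs, argmax = argmax, ignore = ignore,
                 labels = spec$labels, values = spec$values),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s / %s: %d x %d tiles, %d ignored\n",
              x$slide_id, x$feature, x$rows, x$cols, sum(x$ignore)))
  invisible(x)
}

#' Construct a feature map from bare probabilities
#'
#' Mainly for building maps in analyses and tests without running a CNN.
#' @param probs `n_tiles x K` probability matrix, ignore column last;
#'   NA rows mark background-skipped tiles.
#' @param values Numeric class values (length K - 1).
#' @param rows,cols Grid shape; `n_tiles` must equal `rows * cols`
#'   (row-major tile order).
#' @param feature Feature name.
#' @param slide_id Slide identifier.
#' @return A `feature_map`.
#' @export
feature_map <- function(probs, values, rows, cols, feature = "fibrosis",
                        slide_id = "slide") {
  stopifnot(nrow(probs) == rows * cols, ncol(probs) == length(values) + 1)
  labels <- c(as.character(values), "ignore")
  colnames(probs) <- labels
  g <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))[, c("row", "col")]
  argmax <- rep(NA_integer_, nrow(probs))
  ok <- !is.na(probs[, 1])
  argmax[ok] <- max.col(probs[ok, , drop = FALSE])
  ignore <- is.na(argmax) | argmax == ncol(probs)
  structure(list(slide_id = slide_id, feature = feature, rows = rows, cols = cols,
                 tiles = g, probs = probs, argmax = argmax, ignore = ignore,
                 labels = labels, values = as.numeric(values)),
            class = "feature_map")
}

#' Ignore-renormalized weighted class score of one tile
#'
#' Drops the ignore mass, renormalizes over the numeric classes and returns
#' the probability-weighted class value.  Tiles dominated by ignore mass
#' (> 0.5) are flagged missing (NA), keeping tile scores on the
#' pathologist's scale.
#'
#' @param p Probability vector over the numeric classes plus ignore (last).
#' @param values Numeric class values.
#' @return Weighted score, or NA when ignore mass exceeds 0.5.
#' @export
tile_weighted_score <- function(p, values) {
  stopifnot(length(p) == length(values) + 1)
  ign <- p[length(p)]
  if (is.na(ign) || ign > 0.5) return(NA_real_)
  q <- p[seq_along(values)]
  s <- sum(q)
  if (s <= 0) return(NA_real_)
  sum(values * q / s)
}

# All per-tile weighted scores of a map.
map_weighted_scores <- function(fm) {
  apply(fm$probs, 1, tile_weighted_score, values = fm$values)
}

#' Export a feature map to CSV and a heatmap PNG
#'
#' The CSV carries one row per tile (row, col, class probabilities, argmax
#' label, weighted score); the PNG renders the weighted score with a fixed
#' viridis-like colormap scaled to the feature's full score range, ignore
#' tiles transparent.
#'
#' @param fm A `feature_map`.
#' @param path_prefix Output prefix; writes `<prefix>.csv` and
#'   `<prefix>.png`.
#' @param png_px Approximate PNG width in pixels.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_feature_map <- function(fm, path_prefix, png_px = 600L) {
  stopifnot(inherits(fm, "feature_map"))
  ws <- map_weighted_scores(fm)
  df <- data.frame(slide_id = fm$slide_id, feature = fm$feature,
                   row = fm$tiles$row, col = fm$tiles$col)
  pr <- fm$probs
  colnames(pr) <- paste0("p_", fm$labels)
  df <- cbind(df, as.data.frame(round(pr, 6)))
  df$argmax <- ifelse(is.na(fm$argmax), NA, fm$labels[fm$argmax])
  df$weighted_score <- round(ws, 6)
  csv <- paste0(path_prefix, ".csv")
  write.csv(df, csv, row.names = FALSE)

  # heatmap raster: row-major grid, score range fixed to the feature range
  smax <- max(fm$values)
  cmap <- hs_colormap(256)
  rgba <- array(0, c(fm$rows, fm$cols, 4))
  for (i in seq_len(nrow(df))) {
    r <- fm$tiles$row[i] + 1; cc <- fm$tiles$col[i] + 1
    if (!is.na(ws[i])) {
      ci <- 1 + round(clamp(ws[i] / smax, 0, 1) * 255)
      rgba[r, cc, 1:3] <- cmap[ci, ]
      rgba[r, cc, 4] <- 1
    }
  }
  fac <- max(1L, round(png_px / fm$cols))
  big <- rgba[rep(seq_len(fm$rows), each = fac), rep(seq_len(fm$cols), each = fac), ,
              drop = FALSE]
  png_path <- paste0(path_prefix, ".png")
  png::writePNG(big, png_path)
  invisible(c(csv = csv, png = png_path))
}

#' Re-import an exported feature-map CSV
#'
#' @param path CSV written by [export_feature_map()].
#' @return A `feature_map` (probabilities at the export precision).
#' @export
read_feature_map_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pcols <- grep("^p_", names(df), value = TRUE)
  labels <- sub("^p_", "", pcols)
  values <- as.numeric(labels[labels != "ignore"])
  probs <- as.matrix(df[, pcols])
  feature_map(probs, values, rows = max(df$row) + 1L, cols = max(df$col) + 1L,
              feature = df$feature[1], slide_id = df$slide_id[1])
}
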
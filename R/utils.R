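# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and an index, staying in 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)

stopifnot_scalar_in <- function(x, lo, hi, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop(sprintf("%s must be a single number in [%s, %s]", what, lo, hi), call. = FALSE)
  invisible(x)
}

# Per-pixel HSV-style saturation of an H x W x 3 array in [0, 1].
rgb_saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  s
}

# Area-average b x b block downscale of an H x W (x C) array; H, W must be
# divisible by b.  Used for the exact 1:3 low-resolution raster.
block_mean <- function(img, b) {
  d <- dim(img)
  if (d[1] %% b != 0 || d[2] %% b != 0)
    stop("image dimensions must be divisible by the block factor", call. = FALSE)
  h2 <- d[1] %/% b; w2 <- d[2] %/% b
  f <- function(m) {
    a <- aperm(array(m, c(b, h2, b, w2)), c(1, 3, 2, 4))
    matrix(colMeans(matrix(a, b * b)), h2, w2)
  }
  if (length(d) == 2) return(f(img))
  out <- array(0, c(h2, w2, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- f(img[, , k])
  out
}

# Bilinear resize of an H x W x C array (EBImage does the interpolation).
resize_rgb <- function(img, w, h) {
  y <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                       w = w, h = h)
  aperm(EBImage::imageData(y), c(2, 1, 3))
}

# Small fixed viridis-like ramp used by the feature-map heatmaps.
hs_colormap <- function(n = 256) {
  anchors <- c("#440154", "#414487", "#2A788E", "#22A884", "#7AD151", "#FDE725")
  ramp <- colorRamp(anchors)
  ramp(seq(0, 1, length.out = n)) / 255
}

`%||%` <- function(a, b) if (is.null(a)) b else a
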
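# Procedural synthetic histology with exact ground truth.
#
# Everything is rendered at the base resolution of 0.44 um/px; a tile
# requested at a coarser resolution is rendered at integer-factor size and
# area-averaged down.  Tiles of high-resolution features are rendered
# independently per 299 px region (vacuoles are clipped at tile borders so
# the per-tile area fractions are exact); fibrosis collagen topology is
# rendered per 897 px base block, i.e. per low-resolution tile.
#
# The Masson-like palette keeps collagen chromatically separate (blue-green)
# from the pink-red cytoplasm so the color-deconvolution baseline has signal.

.hs_palette <- list(
  tissue   = c(0.87, 0.60, 0.66),
  vacuole  = c(0.975, 0.975, 0.975),
  nucleus  = c(0.38, 0.24, 0.50),
  lympho   = c(0.30, 0.17, 0.42),
  collagen = c(0.22, 0.55, 0.58),
  balloon  = c(0.89, 0.83, 0.95),   # rarefied, faintly basophilic cytoplasm
  balloon_rim = c(0.55, 0.38, 0.52),
  glass    = c(0.985, 0.985, 0.985),
  pen      = list(c(0.10, 0.15, 0.75), c(0.05, 0.45, 0.15), c(0.12, 0.12, 0.12))
)

.hs_base_mpp <- 0.44

#' Steatosis area bins used as CNN classes
#'
#' Fractional vacuole-area bins of width 5 percent: `[0,5), [5,10), ...,
#' [65,70), [70,100]`, as fractions in `[0, 1]`.
#'
#' @return A data.frame with columns `class` (0-based bin index), `lo`, `hi`.
#' @export
steatosis_bins <- function() {
  lo <- c(seq(0, 65, by = 5), 70) / 100
  hi <- c(seq(5, 70, by = 5), 100) / 100
  data.frame(class = seq_along(lo) - 1L, lo = lo, hi = hi)
}

#' Bin index of a steatosis area fraction
#' @param frac Vacuole area fraction in `[0, 1]`.
#' @return 0-based bin index into [steatosis_bins()].
#' @export
steatosis_bin_index <- function(frac) {
  stopifnot(all(frac >= 0 & frac <= 1))
  b <- steatosis_bins()
  idx <- findInterval(frac, b$lo)
  pmin(idx - 1L, nrow(b) - 1L)
}

## ---- mask primitives (linear indices into an H x W canvas) ----

ellipse_idx <- function(H, W, cx, cy, rx, ry, theta = 0,
                        x0 = 1, y0 = 1, x1 = W, y1 = H) {
  x0 <- max(x0, 1); y0 <- max(y0, 1); x1 <- min(x1, W); y1 <- min(y1, H)
  rmax <- max(rx, ry)
  bx0 <- max(x0, floor(cx - rmax)); bx1 <- min(x1, ceiling(cx + rmax))
  by0 <- max(y0, floor(cy - rmax)); by1 <- min(y1, ceiling(cy + rmax))
  if (bx0 > bx1 || by0 > by1) return(integer(0))
  xs <- bx0:bx1; ys <- by0:by1
  DX <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  DY <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  ct <- cos(theta); st <- sin(theta)
  u <- DX * ct + DY * st; v <- -DX * st + DY * ct
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  M <- outer(ys, (xs - 1) * H, "+")
  M[inside]
}

segment_idx <- function(H, W, xa, ya, xb, yb, halfw,
                        x0 = 1, y0 = 1, x1 = W, y1 = H) {
  x0 <- max(x0, 1); y0 <- max(y0, 1); x1 <- min(x1, W); y1 <- min(y1, H)
  bx0 <- max(x0, floor(min(xa, xb) - halfw)); bx1 <- min(x1, ceiling(max(xa, xb) + halfw))
  by0 <- max(y0, floor(min(ya, yb) - halfw)); by1 <- min(y1, ceiling(max(ya, yb) + halfw))
  if (bx0 > bx1 || by0 > by1) return(integer(0))
  xs <- bx0:bx1; ys <- by0:by1
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  vx <- xb - xa; vy <- yb - ya; L2 <- max(vx^2 + vy^2, 1e-9)
  tt <- clamp(((X - xa) * vx + (Y - ya) * vy) / L2, 0, 1)
  d2 <- (X - xa - tt * vx)^2 + (Y - ya - tt * vy)^2
  inside <- d2 <= halfw^2
  M <- outer(ys, (xs - 1) * H, "+")
  M[inside]
}

arc_idx <- function(H, W, cx, cy, R, halfw, a0, a1,
                    x0 = 1, y0 = 1, x1 = W, y1 = H) {
  x0 <- max(x0, 1); y0 <- max(y0, 1); x1 <- min(x1, W); y1 <- min(y1, H)
  r_out <- R + halfw
  bx0 <- max(x0, floor(cx - r_out)); bx1 <- min(x1, ceiling(cx + r_out))
  by0 <- max(y0, floor(cy - r_out)); by1 <- min(y1, ceiling(cy + r_out))
  if (bx0 > bx1 || by0 > by1) return(integer(0))
  xs <- bx0:bx1; ys <- by0:by1
  DX <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  DY <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  r <- sqrt(DX^2 + DY^2)
  ang <- atan2(DY, DX) %% (2 * pi)
  span <- (a1 - a0) %% (2 * pi); if (span == 0) span <- 2 * pi
  rel <- (ang - a0) %% (2 * pi)
  inside <- abs(r - R) <= halfw & rel <= span
  M <- outer(ys, (xs - 1) * H, "+")
  M[inside]
}

## ---- canvas ----

canvas_new <- function(h, w) {
  cv <- new.env(parent = emptyenv())
  cv$h <- h; cv$w <- w
  cv$img <- array(0, c(h, w, 3))
  cv$vac <- matrix(FALSE, h, w)
  cv$col <- matrix(FALSE, h, w)
  cv$foci <- NULL        # focus centers (x, y)
  cv$balloon <- NULL     # ballooned-cell centers
  cv$rim_anchors <- NULL # fibrosis portal-rim anchor points
  cv
}

paint <- function(cv, idx, color, alpha = 1) {
  if (!length(idx)) return(invisible(cv))
  cpp_paint(cv$img, as.integer(idx), color, alpha, runif(1, 0.95, 1.03), cv$h * cv$w)
  invisible(cv)
}

add_tissue <- function(cv, x0 = 1, y0 = 1, x1 = cv$w, y1 = cv$h, speckle = 0.10) {
  base <- clamp(.hs_palette$tissue * (1 + runif(3, -0.04, 0.04)), 0, 1)
  h <- y1 - y0 + 1; w <- x1 - x0 + 1
  mult <- runif(h * w, 1 - speckle, 1 + speckle)
  if (h == cv$h && w == cv$w) {
    cv$img <- array(c(pmin(base[1] * mult, 1), pmin(base[2] * mult, 1),
                      pmin(base[3] * mult, 1)), c(h, w, 3))
  } else {
    mult <- matrix(mult, h, w)
    for (k in 1:3) cv$img[y0:y1, x0:x1, k] <- pmin(base[k] * mult, 1)
  }
  invisible(cv)
}

# Hepatocyte nuclei live in the parenchyma between fat droplets; a nucleus
# painted onto a white droplet would mimic a ballooned cell.
add_scattered_nuclei <- function(cv, n, x0 = 1, y0 = 1, x1 = cv$w, y1 = cv$h) {
  for (i in seq_len(n)) {
    cx <- runif(1, x0, x1); cy <- runif(1, y0, y1)
    if (cv$vac[round(cy), round(cx)]) next
    idx <- ellipse_idx(cv$h, cv$w, cx, cy,
                       runif(1, 2.2, 3.4), runif(1, 2.2, 3.4), runif(1, 0, pi),
                       x0, y0, x1, y1)
    paint(cv, idx, .hs_palette$nucleus * runif(1, 0.9, 1.15))
  }
  invisible(cv)
}

# Greedy macrovesicular droplet placement until the region's vacuole area
# fraction reaches `target`; droplet size shrinks near the target so the
# overshoot stays below ~0.3% of the region.
add_vacuoles <- function(cv, target, x0 = 1, y0 = 1, x1 = cv$w, y1 = cv$h) {
  if (target <= 0) return(0)
  npx <- (x1 - x0 + 1) * (y1 - y0 + 1)
  frac <- sum(cv$vac[y0:y1, x0:x1]) / npx
  it <- 0
  while (frac < target && it < 20000) {
    it <- it + 1
    remaining <- target - frac
    r <- if (remaining > 0.03) runif(1, 16, 40)
         else if (remaining > 0.008) runif(1, 7, 14)
         else runif(1, 3.5, 7)
    cx <- runif(1, x0, x1); cy <- runif(1, y0, y1)
    idx <- ellipse_idx(cv$h, cv$w, cx, cy, r, r * runif(1, 0.75, 1),
                       runif(1, 0, pi), x0, y0, x1, y1)
    if (!length(idx)) next
    fresh <- cpp_mask_set(cv$vac, as.integer(idx))
    if (!fresh) next
    frac <- frac + fresh / npx
    paint(cv, idx, .hs_palette$vacuole * runif(1, 0.985, 1.005))
  }
  frac
}

add_focus <- function(cv, cx, cy) {
  # dense mononuclear infiltrate: many tightly packed dark cells
  # the infiltrate is an aggregate of cells that overlies whatever tissue
  # architecture is present (including fat), so no droplet rejection here
  nd <- sample(18:30, 1)
  for (i in seq_len(nd)) {
    dx <- clamp(rnorm(1, 0, 8), -20, 20); dy <- clamp(rnorm(1, 0, 8), -20, 20)
    idx <- ellipse_idx(cv$h, cv$w, cx + dx, cy + dy,
                       runif(1, 2.6, 4.2), runif(1, 2.6, 4.2), runif(1, 0, pi))
    paint(cv, idx, .hs_palette$lympho * runif(1, 0.75, 1.0))
  }
  cv$foci <- rbind(cv$foci, c(cx, cy))
  invisible(cv)
}

add_balloon_cell <- function(cv, cx, cy) {
  # swollen hepatocyte: large, rarefied pale cytoplasm, distinct membrane,
  # central nucleus — unlike a fat droplet (pure white, rimless, anuclear)
  r <- runif(1, 32, 46)
  body <- ellipse_idx(cv$h, cv$w, cx, cy, r, r * runif(1, 0.85, 1), runif(1, 0, pi))
  paint(cv, body, .hs_palette$balloon)
  rim <- arc_idx(cv$h, cv$w, cx, cy, r * 0.95, 2.8, 0, 2 * pi)
  paint(cv, rim, .hs_palette$balloon_rim, alpha = 0.9)
  nuc <- ellipse_idx(cv$h, cv$w, cx, cy, runif(1, 6, 9), runif(1, 6, 9))
  paint(cv, nuc, .hs_palette$nucleus)
  cv$balloon <- rbind(cv$balloon, c(cx, cy))
  invisible(cv)
}

# Paints collagen and returns the count of newly collagen-positive pixels.
# Mature structural collagen is dense (alpha ~0.85); fine perisinusoidal
# fibrils stain faintly (low alpha), which is why they barely register in
# thresholded collagen-area measurements although they are plainly visible.
paint_collagen <- function(cv, idx, alpha = 0.85) {
  if (!length(idx)) return(0L)
  fresh <- cpp_mask_set(cv$col, as.integer(idx))
  paint(cv, idx, .hs_palette$collagen * runif(1, 0.92, 1.08), alpha = alpha)
  fresh
}

# Collagen topology per fibrosis stage, rendered inside one block region.
# Area calibration (fraction of the block): every stage carries a normal
# portal-tract background drawn from U(0.002, 0.018) — wide between-slide
# variability.  Stage 1 adds perisinusoidal thread bundles over only
# U(0.0008, 0.0018) of the block — far inside the stage-0 variability, so
# the area-only baseline cannot separate stage 1 from stage 0 although
# the striped texture is visible.  Stages >= 2 add dense structural
# collagen that markedly raises the area.
add_fibrosis_pattern <- function(cv, class, x0 = 1, y0 = 1, x1 = cv$w, y1 = cv$h,
                                 target = NULL) {
  class <- as.integer(class)
  base <- runif(1, 0.002, 0.018)
  target <- target %||% switch(as.character(class),
                               "0" = base,
                               "1" = base + runif(1, 1e-3, 1.8e-3),
                               "2" = runif(1, 0.020, 0.040),
                               "3" = runif(1, 0.045, 0.075),
                               "4" = runif(1, 0.085, 0.145))
  # the region may be a virtual block extending beyond the canvas (a tile
  # seeing a fragment of a slide-level block); painting clips to the canvas
  # and the area target applies to the visible window, which under uniform
  # primitive placement matches the full block's expected coverage
  npx <- (min(x1, cv$w) - max(x0, 1) + 1) * (min(y1, cv$h) - max(y0, 1) + 1)
  n_set <- sum(cv$col[max(y0, 1):min(y1, cv$h), max(x0, 1):min(x1, cv$w)])
  pc <- function(idx) n_set <<- n_set + paint_collagen(cv, idx)
  frac <- function() n_set / npx
  m <- 60  # margin for anchors
  n_anchor <- sample(2:4, 1)
  ax <- runif(n_anchor, x0 + m, x1 - m); ay <- runif(n_anchor, y0 + m, y1 - m)
  cv$rim_anchors <- rbind(cv$rim_anchors, cbind(ax, ay)[1:2, , drop = FALSE])
  speck <- function() {
    # portal-tract collagen: few compact masses hugging the anchors (not
    # speckle dust, which would mimic perisinusoidal texture downscaled)
    a <- sample(n_anchor, 1)
    pc(ellipse_idx(cv$h, cv$w, ax[a] + rnorm(1, 0, 12), ay[a] + rnorm(1, 0, 12),
                                   runif(1, 12, 30), runif(1, 10, 22), runif(1, 0, pi),
                                   x0, y0, x1, y1))
  }
  thread <- function() {
    # perisinusoidal collagen runs along sinusoid tracks, which are spaced
    # about one hepatocyte apart (~10 um): widely spaced parallel strands.
    # The wide period matters: it keeps the striped pattern resolvable
    # after the low-resolution downscale instead of aliasing into a smudge.
    cx <- runif(1, x0, x1); cy <- runif(1, y0, y1)
    th <- runif(1, 0, 2 * pi)
    px <- -sin(th); py <- cos(th)          # perpendicular offset direction
    for (b in seq_len(sample(5:6, 1))) {
      off <- (b - 1) * runif(1, 22, 26)
      bx <- cx + off * px; by <- cy + off * py
      L <- runif(1, 45, 60)
      pc(segment_idx(cv$h, cv$w, bx, by, bx + L * cos(th), by + L * sin(th),
                     runif(1, 2.2, 2.8), x0, y0, x1, y1))
    }
  }
  rim <- function(a = sample(n_anchor, 1)) {
    a0 <- runif(1, 0, 2 * pi)
    pc(arc_idx(cv$h, cv$w, ax[a], ay[a], runif(1, 45, 75),
                               runif(1, 2.5, 4), a0, a0 + runif(1, 3.5, 5.8),
                               x0, y0, x1, y1))
  }
  streak <- function(xa, ya, xb, yb) {
    # curved bridge as a 3-segment polyline through jittered midpoints
    mx1 <- xa + (xb - xa) / 3 + rnorm(1, 0, 30); my1 <- ya + (yb - ya) / 3 + rnorm(1, 0, 30)
    mx2 <- xa + 2 * (xb - xa) / 3 + rnorm(1, 0, 30); my2 <- ya + 2 * (yb - ya) / 3 + rnorm(1, 0, 30)
    hw <- runif(1, 3, 4.5)
    pts <- rbind(c(xa, ya), c(mx1, my1), c(mx2, my2), c(xb, yb))
    for (s in 1:3)
      pc(segment_idx(cv$h, cv$w, pts[s, 1], pts[s, 2],
                                     pts[s + 1, 1], pts[s + 1, 2], hw, x0, y0, x1, y1))
  }
  ring <- function() {
    R <- runif(1, 85, 135)
    cx <- runif(1, x0 + R, x1 - R); cy <- runif(1, y0 + R, y1 - R)
    pc(arc_idx(cv$h, cv$w, cx, cy, R, runif(1, 3.5, 5.5), 0, 2 * pi,
                               x0, y0, x1, y1))
    c(cx, cy)
  }

  # mandatory stage-defining structures first
  if (class >= 2) { rim(1); rim(2); if (n_anchor > 2) rim(3) }
  if (class == 3) streak(ax[1], ay[1], ax[2], ay[2])
  if (class == 4) {
    centers <- ring(); centers <- rbind(centers, ring())
    streak(centers[1, 1], centers[1, 2], centers[2, 1], centers[2, 2])
  }
  # normal portal background up to `base` ...
  it <- 0
  for (i in seq_len(n_anchor)) speck()
  while (frac() < min(base, target) && it < 1000) { it <- it + 1; speck() }
  # ... then stage-appropriate filler up to the area target
  it <- 0
  while (frac() < target && it < 3000) {
    it <- it + 1
    switch(as.character(class),
           "0" = speck(),
           "1" = thread(),
           "2" = { rim(); if (it %% 4 == 0) speck() },
           "3" = { rim(); if (it %% 3 == 0) streak(runif(1, x0 + m, x1 - m), runif(1, y0 + m, y1 - m),
                                                   runif(1, x0 + m, x1 - m), runif(1, y0 + m, y1 - m)) },
           "4" = { ring(); if (it %% 2 == 0) thread() })
  }
  invisible(cv)
}

render_ignore_tile <- function(cv, kind = c("blank", "edge", "pen")) {
  kind <- match.arg(kind)
  h <- cv$h; w <- cv$w
  glass <- clamp(.hs_palette$glass[1] + matrix(rnorm(h * w, 0, 0.008), h, w), 0, 1)
  if (kind == "blank") {
    for (k in 1:3) cv$img[, , k] <- glass
  } else if (kind == "edge") {
    add_tissue(cv)
    add_scattered_nuclei(cv, round(30 * h * w / 299^2))
    # wavy fragment edge: glass beyond a sinusoidal boundary
    xs <- seq_len(w)
    cut <- h * runif(1, 0.3, 0.6) + h * 0.1 * sin(xs / w * runif(1, 2, 5) * pi + runif(1, 0, pi))
    rowm <- matrix(seq_len(h), h, w)
    cutm <- matrix(cut, h, w, byrow = TRUE)
    side <- sample(c(TRUE, FALSE), 1)
    mask <- if (side) rowm < cutm else rowm > cutm
    for (k in 1:3) { ch <- cv$img[, , k]; ch[mask] <- glass[mask]; cv$img[, , k] <- ch }
  } else {
    if (runif(1) < 0.5) add_tissue(cv) else for (k in 1:3) cv$img[, , k] <- glass
    pen <- .hs_palette$pen[[sample(3, 1)]]
    xa <- runif(1, 1, w); xb <- runif(1, 1, w)
    paint(cv, segment_idx(h, w, xa, 1, xb, h, runif(1, 12, 30)), pen, alpha = 0.9)
  }
  invisible(cv)
}

## ---- tile generation ----

valid_tile_classes <- function(feature) {
  switch(feature,
         ballooning   = 0:1,
         inflammation = 0:2,
         steatosis    = steatosis_bins()$class,
         fibrosis     = 0:4)
}

# Nuisance co-pathology distribution matched to the cohort generator, so
# training tiles of one feature carry the background variation the other
# features produce on whole slides (vacuole burdens up to severe steatosis,
# foci, ballooned cells, and fibrous collagen structures crossing tiles).
nuisance_steatosis_target <- function() {
  if (runif(1) < 0.3) runif(1, 0, 0.05) else runif(1, 0.05, 0.85)
}

add_nuisance <- function(cv, feature, x0 = 1, y0 = 1, x1 = cv$w, y1 = cv$h,
                         steatosis_target = NULL, severe = FALSE) {
  # severe = hard-case co-pathology (heavy steatosis, infiltrate and
  # collagen all present), used to mine hard negative training tiles the
  # way an annotate-train-review loop would focus on challenging cases
  if (feature != "steatosis" && (severe || runif(1) < 0.8))
    add_vacuoles(cv, steatosis_target %||%
                   (if (severe) runif(1, 0.45, 0.85) else nuisance_steatosis_target()),
                 x0, y0, x1, y1)
  if (feature != "inflammation" && (severe || runif(1) < 0.3))
    for (i in seq_len(sample(if (severe) 2:3 else 1:2, 1)))
      add_focus(cv, runif(1, x0, x1), runif(1, y0, y1))
  if (!feature %in% c("ballooning", "steatosis") && runif(1) < 0.15)
    add_balloon_cell(cv, runif(1, x0 + 40, x1 - 40), runif(1, y0 + 40, y1 - 40))
  if (feature != "fibrosis" && (severe || runif(1) < 0.5)) {
    # slide-level fibrosis structures cross high tiles as fragments: draw
    # the pattern on a virtual 897 px block and let the tile be a random
    # window into it
    ox <- sample(0:598, 1); oy <- sample(0:598, 1)
    cls <- if (severe) sample(2:4, 1) else sample(0:4, 1)
    add_fibrosis_pattern(cv, cls,
                         x0 - ox, y0 - oy, x0 - ox + 896, y0 - oy + 896)
  }
  invisible(cv)
}

#' Generate one synthetic labeled tile
#'
#' Renders the defining morphology of one class of one histological feature:
#' steatosis bins fill the requested vacuole area fraction with white
#' macrovesicular droplets; inflammation classes 0/1/2 place 0, 1-2 or >= 3
#' lymphocyte clusters; ballooning class 1 places at least one enlarged pale
#' hepatocyte with a central nucleus; fibrosis classes render blue-green
#' collagen with stage-dependent topology (portal specks, perisinusoidal
#' threads, periportal rims, bridging streaks, cirrhotic rings).  The
#' `"ignore"` class renders blank glass, a fragment edge, or a pen mark.
#' Tiles of one feature carry nuisance co-pathology of the others.
#'
#' @param feature `"ballooning"`, `"inflammation"`, `"steatosis"` or
#'   `"fibrosis"`.
#' @param class_label Integer class valid for the feature, or `"ignore"`.
#' @param tile_px Tile side in pixels (default 299).
#' @param mpp Physical resolution; must be an integer multiple of 0.44 um/px
#'   (0.44 renders natively, 1.32 renders at 3x and area-averages down).
#' @param seed Integer seed; the tile is deterministic given all arguments.
#' @param co_pathology `"cohort"` draws nuisance co-pathology from the
#'   cohort-like distribution; `"severe"` forces heavy co-pathology
#'   (hard-case mining for training negatives).
#' @return An `tile_px x tile_px x 3` RGB array in `[0, 1]` with attributes
#'   `label` (as character), `vacuole_frac`, and base-resolution mask
#'   attributes `vacuole_mask`, `collagen_mask`, plus `foci`, `balloon`
#'   (centers) and `rim_anchors` — the generator's shape ledger.
#' @export
generate_tile <- function(feature, class_label, tile_px = 299L,
                          mpp = .hs_base_mpp, seed = 1L,
                          co_pathology = c("cohort", "severe")) {
  co_pathology = match.arg(co_pathology)
  feature <- match_feature(feature)
  factor <- mpp / .hs_base_mpp
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("mpp must be a positive integer multiple of 0.44 um/px", call. = FALSE)
  factor <- as.integer(round(factor))
  ignore <- identical(class_label, "ignore")
  if (!ignore) {
    class_label <- suppressWarnings(as.integer(class_label))
    if (is.na(class_label) || !class_label %in% valid_tile_classes(feature))
      stop(sprintf("invalid class '%s' for feature '%s' (valid: %s, ignore)",
                   class_label, feature,
                   paste(range(valid_tile_classes(feature)), collapse = "-")),
           call. = FALSE)
  }
  hb <- tile_px * factor
  with_seed(seed, {
    cv <- canvas_new(hb, hb)
    if (ignore) {
      render_ignore_tile(cv, sample(c("blank", "edge", "pen"), 1))
    } else {
      add_tissue(cv)
      if (feature == "steatosis") {
        b <- steatosis_bins()[class_label + 1, ]
        lo <- b$lo; hi <- min(b$hi, 0.88)
        target <- runif(1, lo + 0.004, hi - 0.004)
        add_vacuoles(cv, target)
        add_nuisance(cv, feature, severe = co_pathology == "severe")
      } else if (feature == "inflammation") {
        k <- switch(as.character(class_label), "0" = 0L, "1" = sample(1:2, 1), "2" = sample(3:5, 1))
        add_nuisance(cv, feature, severe = co_pathology == "severe")
        # anywhere in the tile, borders included, exactly as on slides
        for (i in seq_len(k)) add_focus(cv, runif(1, 1, hb), runif(1, 1, hb))
      } else if (feature == "ballooning") {
        add_nuisance(cv, feature, severe = co_pathology == "severe")
        k <- if (class_label == 1) sample(1:2, 1) else 0L
        for (i in seq_len(k)) add_balloon_cell(cv, runif(1, 1, hb), runif(1, 1, hb))
      } else { # fibrosis
        # one slide-level steatosis burden shared by all subtiles, as on
        # real slides
        st <- nuisance_steatosis_target()
        nsub <- hb %/% 299L
        if (nsub >= 1) {
          for (r in seq_len(nsub)) for (cc in seq_len(nsub))
            add_nuisance(cv, feature, (cc - 1) * 299 + 1, (r - 1) * 299 + 1,
                         cc * 299, r * 299, steatosis_target = st)
        } else add_nuisance(cv, feature, steatosis_target = st)
        add_fibrosis_pattern(cv, class_label)
      }
      if (feature != "inflammation" || !ignore)
        add_scattered_nuclei(cv, round(30 * (hb / 299)^2))
    }
    img <- cv$img
    if (factor > 1) img <- block_mean(img, factor)
    structure(img,
              label = if (ignore) "ignore" else as.character(class_label),
              vacuole_frac = sum(cv$vac) / (hb * hb),
              vacuole_mask = cv$vac,
              collagen_mask = cv$col,
              foci = cv$foci, balloon = cv$balloon,
              rim_anchors = cv$rim_anchors)
  })
}

## ---- slide generation ----

#' Specification of a synthetic slide
#'
#' @param slide_id Character identifier.
#' @param width_px,height_px Slide size in pixels at `mpp` (>= 299).
#' @param mpp Resolution, must equal 0.44 um/px (the base resolution).
#' @param steatosis_area_frac Target macrovesicular vacuole area fraction.
#' @param inflam_foci_per_field Expected inflammatory foci per 200x field
#'   (a 660 um square).
#' @param ballooning_burden `"none"`, `"few"` or `"many"`.
#' @param fibrosis_class Integer fibrosis stage 0-4.
#' @param observer_noise_sd Recorded-score noise (used by [generate_cohort()]).
#' @param seed Integer seed.
#' @return A `synthetic_slide_spec` object.
#' @export
synthetic_slide_spec <- function(slide_id = "synthetic",
                                 width_px = 1794L, height_px = 1794L,
                                 mpp = .hs_base_mpp,
                                 steatosis_area_frac = 0,
                                 inflam_foci_per_field = 0,
                                 ballooning_burden = c("none", "few", "many"),
                                 fibrosis_class = 0L,
                                 observer_noise_sd = 0,
                                 seed = 1L) {
  ballooning_burden <- match.arg(ballooning_burden)
  if (width_px < 299 || height_px < 299)
    stop("slide must be at least one 299 px tile in each dimension", call. = FALSE)
  stopifnot_scalar_in(steatosis_area_frac, 0, 1, "steatosis_area_frac")
  stopifnot_scalar_in(inflam_foci_per_field, 0, Inf, "inflam_foci_per_field")
  if (!fibrosis_class %in% 0:4) stop("fibrosis_class must be in 0..4", call. = FALSE)
  stopifnot_scalar_in(observer_noise_sd, 0, Inf, "observer_noise_sd")
  if (abs(mpp - .hs_base_mpp) > 1e-9)
    stop("synthetic slides are rendered at the 0.44 um/px base resolution", call. = FALSE)
  structure(list(slide_id = as.character(slide_id),
                 width_px = as.integer(width_px), height_px = as.integer(height_px),
                 mpp = mpp,
                 steatosis_area_frac = steatosis_area_frac,
                 inflam_foci_per_field = inflam_foci_per_field,
                 ballooning_burden = ballooning_burden,
                 fibrosis_class = as.integer(fibrosis_class),
                 observer_noise_sd = observer_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Ballooned-cell density (cells per mm^2) for a burden level; the few/many
# convention (1-3 = few, > 3 = many per mm^2) is the generator's own.
balloon_density_for <- function(burden) {
  switch(burden, none = 0, few = runif(1, 1, 3), many = runif(1, 3.5, 8))
}

# 200x field modeled as a 660 um square.
.hs_field_um <- 660

#' Render a synthetic slide in memory
#'
#' Deterministic for a fixed spec.  Realized inflammatory-focus and
#' ballooned-cell counts are the generative density times the slide area,
#' rounded up for nonzero density, so slide-level ground truth is an exact
#' function of the spec.
#'
#' @param spec A [synthetic_slide_spec()].
#' @param keep_masks Keep the slide-level vacuole/collagen masks (large).
#' @return A list with `slide` (a [slide_image()]) and `truth` (list with
#'   `slide_scores`, `per_tile_labels`, `tile_vacuole_frac`,
#'   `generative_params`), plus `masks` when requested.
#' @export
render_slide <- function(spec, keep_masks = FALSE) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  H <- spec$height_px; W <- spec$width_px
  tp <- .hs_geometry$tile_px
  tr <- H %/% tp; tc <- W %/% tp          # high-resolution grid
  lb <- tp * 3L                           # low-tile block in base px
  lr <- H %/% lb; lc <- W %/% lb
  with_seed(spec$seed, {
    cv <- canvas_new(H, W)
    add_tissue(cv)
    tile_frac <- matrix(0, max(tr, 1), max(tc, 1))
    for (r in seq_len(tr)) for (cc in seq_len(tc)) {
      tile_frac[r, cc] <- add_vacuoles(cv, spec$steatosis_area_frac,
                                       (cc - 1) * tp + 1, (r - 1) * tp + 1,
                                       cc * tp, r * tp)
    }
    # remainder margins get tissue-only texture (already painted)
    add_scattered_nuclei(cv, round(30 * (H / tp) * (W / tp)))

    area_mm2 <- (H * spec$mpp / 1000) * (W * spec$mpp / 1000)
    n_fields <- (H * spec$mpp / .hs_field_um) * (W * spec$mpp / .hs_field_um)
    n_foci <- if (spec$inflam_foci_per_field > 0)
      as.integer(ceiling(spec$inflam_foci_per_field * n_fields)) else 0L
    bdens <- balloon_density_for(spec$ballooning_burden)
    n_balloon <- if (bdens > 0) as.integer(ceiling(bdens * area_mm2)) else 0L

    m <- 35
    foci_xy <- if (n_foci) cbind(runif(n_foci, m, W - m), runif(n_foci, m, H - m)) else NULL
    for (i in seq_len(n_foci)) add_focus(cv, foci_xy[i, 1], foci_xy[i, 2])
    bal_xy <- if (n_balloon) cbind(runif(n_balloon, 45, W - 45), runif(n_balloon, 45, H - 45)) else NULL
    for (i in seq_len(n_balloon)) add_balloon_cell(cv, bal_xy[i, 1], bal_xy[i, 2])

    for (r in seq_len(max(lr, 1))) for (cc in seq_len(max(lc, 1))) {
      if (lr >= 1 && lc >= 1)
        add_fibrosis_pattern(cv, spec$fibrosis_class,
                             (cc - 1) * lb + 1, (r - 1) * lb + 1,
                             min(cc * lb, W), min(r * lb, H))
    }
    if (lr < 1 || lc < 1)  # slide smaller than one low tile: pattern over all
      add_fibrosis_pattern(cv, spec$fibrosis_class)

    count_in_tile <- function(xy, px) {
      out <- matrix(0L, max(H %/% px, 1), max(W %/% px, 1))
      if (is.null(xy)) return(out)
      rr <- pmin(floor(xy[, 2] / px) + 1, nrow(out))
      cc2 <- pmin(floor(xy[, 1] / px) + 1, ncol(out))
      for (i in seq_along(rr)) out[rr[i], cc2[i]] <- out[rr[i], cc2[i]] + 1L
      out
    }
    foci_per_tile <- count_in_tile(foci_xy, tp)[seq_len(max(tr, 1)), seq_len(max(tc, 1)), drop = FALSE]
    bal_per_tile <- count_in_tile(bal_xy, tp)[seq_len(max(tr, 1)), seq_len(max(tc, 1)), drop = FALSE]

    per_tile <- list(
      ballooning   = matrix(as.integer(bal_per_tile > 0), nrow(bal_per_tile)),
      inflammation = matrix(ifelse(foci_per_tile == 0, 0L,
                                   ifelse(foci_per_tile <= 2, 1L, 2L)), nrow(foci_per_tile)),
      steatosis    = matrix(steatosis_bin_index(as.vector(tile_frac)), nrow(tile_frac)),
      fibrosis     = matrix(spec$fibrosis_class, max(lr, 0), max(lc, 0))
    )
    scores <- c(
      ballooning   = match(spec$ballooning_burden, c("none", "few", "many")) - 1L,
      inflammation = kleiner_inflammation_score(spec$inflam_foci_per_field),
      steatosis    = kleiner_steatosis_score(100 * spec$steatosis_area_frac),
      fibrosis     = spec$fibrosis_class
    )
    out <- list(
      slide = slide_image(cv$img, spec$slide_id, spec$mpp),
      truth = list(slide_scores = scores,
                   per_tile_labels = per_tile,
                   tile_vacuole_frac = tile_frac,
                   n_foci = n_foci, n_balloon = n_balloon,
                   generative_params = spec)
    )
    if (keep_masks) out$masks <- list(vacuole = cv$vac, collagen = cv$col)
    out
  })
}

#' Generate a synthetic slide TIFF with ground truth
#'
#' @param spec A [synthetic_slide_spec()].
#' @param path Output TIFF path.
#' @return A list with `path` and `truth` (see [render_slide()]).
#' @export
generate_slide <- function(spec, path) {
  r <- render_slide(spec)
  write_slide(r$slide, path)
  list(path = path, truth = r$truth)
}

#' Per-tile ground-truth labels as a table
#'
#' @param slide_id Slide identifier.
#' @param truth The `truth` element of [render_slide()].
#' @return data.frame with columns slide_id, feature, row, col, label.
#' @export
tile_labels_table <- function(slide_id, truth) {
  do.call(rbind, lapply(names(truth$per_tile_labels), function(f) {
    m <- truth$per_tile_labels[[f]]
    if (!length(m)) return(NULL)
    data.frame(slide_id = slide_id, feature = f,
               row = as.vector(row(m)) - 1L, col = as.vector(col(m)) - 1L,
               label = as.vector(m))
  }))
}

## ---- cohort generation ----

draw_cohort_scores <- function(n, score_mix) {
  if (identical(score_mix, "uniform")) {
    data.frame(ballooning = sample(0:2, n, TRUE),
               inflammation = sample(0:3, n, TRUE),
               steatosis = sample(0:3, n, TRUE),
               fibrosis = sample(0:4, n, TRUE))
  } else if (is.data.frame(score_mix)) {
    need <- c("ballooning", "inflammation", "steatosis", "fibrosis")
    if (!all(need %in% names(score_mix)))
      stop("score_mix data.frame needs columns ", paste(need, collapse = ", "), call. = FALSE)
    p <- score_mix$prob %||% rep(1, nrow(score_mix))
    if (any(p < 0) || sum(p) <= 0) stop("invalid score_mix distribution", call. = FALSE)
    score_mix[sample(nrow(score_mix), n, TRUE, prob = p / sum(p)), need]
  } else stop("score_mix must be \"uniform\" or a data.frame", call. = FALSE)
}

params_for_scores <- function(sc) {
  st_frac <- switch(as.character(sc$steatosis),
                    "0" = runif(1, 0.002, 0.045), "1" = runif(1, 0.05, 0.33),
                    "2" = runif(1, 0.333, 0.66), "3" = runif(1, 0.663, 0.85))
  fpf <- switch(as.character(sc$inflammation),
                "0" = 0, "1" = runif(1, 0.3, 1.9), "2" = runif(1, 2, 4), "3" = runif(1, 4.1, 8))
  burden <- c("none", "few", "many")[sc$ballooning + 1]
  list(steatosis_area_frac = st_frac, inflam_foci_per_field = fpf,
       ballooning_burden = burden, fibrosis_class = sc$fibrosis)
}

#' Generate a synthetic cohort with a score manifest
#'
#' Draws per-slide pathologist scores from `score_mix`, derives generative
#' parameters inside each score's defining interval, optionally renders and
#' writes the slide TIFFs, and returns the manifest.  With
#' `observer_noise_sd > 0` the recorded discrete scores are perturbed by
#' +/- 1 with probability `2 * pnorm(-0.5 / sd)` (a normally distributed
#' reading error that rounds to the neighboring score), clipped to range,
#' emulating inter-observer variability; the noiseless truth stays in the
#' `truth_*` columns.
#'
#' @param n_slides Number of slides (>= 1).
#' @param dir Output directory for TIFFs (created); required when
#'   `write_images` is TRUE.
#' @param score_mix `"uniform"` or a data.frame with columns ballooning,
#'   inflammation, steatosis, fibrosis and optional prob.
#' @param observer_noise_sd Observer noise level (0 = scores recorded exactly).
#' @param seed Integer seed.
#' @param width_px,height_px Slide size in px at 0.44 um/px.
#' @param write_images Render and write TIFFs; if FALSE, `path` is NA and
#'   slides can be re-rendered on demand from the attached specs.
#' @param train_frac Fraction of slides labeled "train" in the split column.
#' @return Manifest data.frame (slide_id, path, ballooning, inflammation,
#'   steatosis, fibrosis, split, truth and generative columns) with the
#'   per-slide [synthetic_slide_spec()]s in `attr(, "specs")`.
#' @export
generate_cohort <- function(n_slides, dir = NULL, score_mix = "uniform",
                            observer_noise_sd = 0, seed = 1L,
                            width_px = 1794L, height_px = 1794L,
                            write_images = TRUE, train_frac = 0.75) {
  if (!is_count(n_slides) || n_slides < 1) stop("n_slides must be >= 1", call. = FALSE)
  if (write_images) {
    if (is.null(dir)) stop("dir required when write_images = TRUE", call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  with_seed(seed, {
    sc <- draw_cohort_scores(n_slides, score_mix)
    rows <- vector("list", n_slides); specs <- vector("list", n_slides)
    p_flip <- if (observer_noise_sd > 0) 2 * stats::pnorm(-0.5 / observer_noise_sd) else 0
    for (i in seq_len(n_slides)) {
      pars <- params_for_scores(sc[i, ])
      id <- sprintf("synth%04d", i)
      spec <- synthetic_slide_spec(id, width_px, height_px,
                                   steatosis_area_frac = pars$steatosis_area_frac,
                                   inflam_foci_per_field = pars$inflam_foci_per_field,
                                   ballooning_burden = pars$ballooning_burden,
                                   fibrosis_class = pars$fibrosis_class,
                                   observer_noise_sd = observer_noise_sd,
                                   seed = child_seed(seed, i))
      specs[[i]] <- spec
      path <- NA_character_
      if (write_images) {
        path <- file.path(dir, paste0(id, ".tif"))
        generate_slide(spec, path)
      }
      truth <- c(ballooning = sc$ballooning[i], inflammation = sc$inflammation[i],
                 steatosis = sc$steatosis[i], fibrosis = sc$fibrosis[i])
      recorded <- truth
      ranges <- .hs_ranges[names(truth)]
      for (f in seq_along(recorded)) {
        if (p_flip > 0 && runif(1) < p_flip)
          recorded[f] <- clamp(recorded[f] + sample(c(-1L, 1L), 1), 0L, ranges[f])
      }
      rows[[i]] <- data.frame(
        slide_id = id, path = path,
        ballooning = recorded[["ballooning"]], inflammation = recorded[["inflammation"]],
        steatosis = recorded[["steatosis"]], fibrosis = recorded[["fibrosis"]],
        split = NA_character_,
        truth_ballooning = truth[["ballooning"]], truth_inflammation = truth[["inflammation"]],
        truth_steatosis = truth[["steatosis"]], truth_fibrosis = truth[["fibrosis"]],
        gen_steatosis_frac = pars$steatosis_area_frac,
        gen_fpf = pars$inflam_foci_per_field,
        gen_ballooning_burden = pars$ballooning_burden,
        gen_fibrosis_class = pars$fibrosis_class,
        gen_seed = spec$seed)
    }
    manifest <- do.call(rbind, rows)
    n_train <- round(train_frac * n_slides)
    manifest$split <- "test"
    manifest$split[sample(n_slides, n_train)] <- "train"
    attr(manifest, "specs") <- specs
    manifest
  })
}

#' Bulk labeled training tiles for one classifier
#'
#' Generates `n_per_class` synthetic tiles for every class of a classifier
#' spec (including ignore) and returns them already resized to the CNN input
#' size, ready for [train_classifier()].
#'
#' @param spec A [classifier_spec()].
#' @param n_per_class Tiles per class.
#' @param seed Integer seed.
#' @param classes Optional subset of class labels (characters).
#' @param hard_negative_frac Fraction of each *lowest-class* tile batch
#'   rendered with severe co-pathology (hard-case mining; the challenging
#'   negatives are tiles dense in the other features).
#' @return list with `x` (`input_px^2 x 3 x N` array) and `y` (character labels).
#' @export
synthetic_training_tiles <- function(spec, n_per_class, seed = 1L, classes = NULL,
                                     hard_negative_frac = 0) {
  stopifnot(inherits(spec, "classifier_spec"))
  classes <- classes %||% spec$labels
  mpp <- if (spec$scale == "low") .hs_geometry$mpp_low else .hs_geometry$mpp_high
  n_total <- n_per_class * length(classes)
  X <- array(0, c(spec$input_px, spec$input_px, 3, n_total))
  y <- character(n_total)
  k <- 0
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      severe <- cl == classes[1] && cl != "ignore" &&
        i <= round(hard_negative_frac * n_per_class)
      tl <- generate_tile(spec$feature, if (cl == "ignore") "ignore" else cl,
                          tile_px = spec$tile_px, mpp = mpp,
                          seed = child_seed(seed, k),
                          co_pathology = if (severe) "severe" else "cohort")
      X[, , , k] <- tile_to_input(unclass_tile(tl), spec$input_px)
      y[k] <- attr(tl, "label")
    }
  }
  list(x = X, y = y)
}

unclass_tile <- function(tl) {
  attributes(tl) <- list(dim = dim(tl))
  tl
}
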
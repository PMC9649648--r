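# Classical (non-deep-learning) quantification: Kleiner rule mappings,
# steatosis vacuole-area measurement, collagen area by color deconvolution,
# and the per-stage group comparison against controls.

#' Kleiner steatosis score from vacuole area percent
#'
#' Threshold mapping 0 (< 5%), 1 (5-33%), 2 (> 33-66%), 3 (> 66%).  The
#' printed intervals share their endpoints; ties resolve to the lower score
#' (closed below, open above).
#'
#' @param area_pct Steatosis area coverage in percent, in `[0, 100]`.
#' @return Integer score(s) 0-3.
#' @export
kleiner_steatosis_score <- function(area_pct) {
  if (any(!is.finite(area_pct)) || any(area_pct < 0 | area_pct > 100))
    stop("area_pct must be in [0, 100]", call. = FALSE)
  as.integer(ifelse(area_pct < 5, 0L,
              ifelse(area_pct <= 33, 1L,
               ifelse(area_pct <= 66, 2L, 3L))))
}

#' Kleiner lobular inflammation score from foci per 200x field
#'
#' Threshold mapping 0 (no foci), 1 (< 2 foci), 2 (2-4 foci), 3 (> 4 foci
#' per 200x field).
#'
#' @param foci_per_field Non-negative focus count (may be fractional for an
#'   overall assessment).
#' @return Integer score(s) 0-3.
#' @export
kleiner_inflammation_score <- function(foci_per_field) {
  if (any(!is.finite(foci_per_field)) || any(foci_per_field < 0))
    stop("foci_per_field must be >= 0", call. = FALSE)
  as.integer(ifelse(foci_per_field == 0, 0L,
              ifelse(foci_per_field < 2, 1L,
               ifelse(foci_per_field <= 4, 2L, 3L))))
}

#' Kleiner ballooning score
#'
#' Maps a burden level (`"none"`/`"few"`/`"many"`) or a ballooned-cell
#' density (cells per mm^2; 0 = none, (0, 3] = few, > 3 = many — the
#' package's stated convention for the verbal scale) to scores 0/1/2.
#'
#' @param burden Character level or numeric density per mm^2.
#' @return Integer score(s) 0-2.
#' @export
kleiner_ballooning_score <- function(burden) {
  if (is.character(burden)) {
    if (!all(burden %in% c("none", "few", "many")))
      stop("burden must be none/few/many or a density", call. = FALSE)
    return(as.integer(match(burden, c("none", "few", "many")) - 1L))
  }
  if (any(!is.finite(burden)) || any(burden < 0))
    stop("density must be >= 0", call. = FALSE)
  as.integer(ifelse(burden == 0, 0L, ifelse(burden <= 3, 1L, 2L)))
}

## ---- tissue / vacuole segmentation ----

# Stained tissue: saturated, non-glass pixels.  Vacuoles and glass are both
# bright and unsaturated; a white component counts as a vacuole (cluster)
# when the halo of pixels immediately around it is predominantly stained
# tissue — droplets are embedded in tissue, glass expanses are not.  This
# also handles droplets clipped by the image border, where hole-filling
# fails.  Tissue area = stained pixels plus their embedded vacuoles.
tissue_vacuole_masks <- function(img, sat_threshold = 0.08, bright = 0.85,
                                 min_droplet_px = 40, halo_frac = 0.3) {
  s <- rgb_saturation(img)
  v <- pmax(img[, , 1], img[, , 2], img[, , 3])
  stained <- s > sat_threshold & v < 0.97
  white <- v > bright & s < 0.15
  vac <- white & FALSE
  if (any(white)) {
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(white)))))
    brush <- EBImage::makeBrush(3, "box")
    labd <- t(EBImage::imageData(EBImage::dilate(
      EBImage::Image(t(lab)), brush)))
    halo <- labd > 0 & !white
    halo_tot <- tabulate(labd[halo], nbins = max(lab))
    halo_stn <- tabulate(labd[halo & stained], nbins = max(lab))
    sizes <- tabulate(lab, nbins = max(lab))
    good <- which(sizes >= min_droplet_px & halo_tot > 0 &
                  halo_stn / pmax(halo_tot, 1) >= halo_frac)
    vac <- matrix(lab %in% good, nrow(lab))
  }
  list(tissue = stained | vac, vacuole = vac)
}

#' Macrovesicular steatosis area fraction of an image
#'
#' Segments white, unsaturated droplets enclosed in stained tissue
#' (brightness + low-saturation mask, hole-filled tissue support, component
#' size filter for macrovesicular droplets) and returns the vacuole area as
#' percent of tissue area (tissue including its vacuoles).
#'
#' @param img RGB array or [slide_image()].
#' @param sat_threshold Saturation above which a pixel counts as stained.
#' @param min_droplet_px Minimum droplet component size in px.
#' @return Percent in `[0, 100]`, or `NA` (flagged missing) when the image
#'   contains no tissue.
#' @export
steatosis_area_fraction <- function(img, sat_threshold = 0.08, min_droplet_px = 40) {
  if (inherits(img, "slide_image")) img <- img$pixels
  m <- tissue_vacuole_masks(img, sat_threshold, min_droplet_px = min_droplet_px)
  n_tissue <- sum(m$tissue)
  if (n_tissue < 100) return(NA_real_)
  100 * sum(m$vacuole) / n_tissue
}

## ---- color deconvolution ----

#' Stain model for color deconvolution
#'
#' @param vectors 3 x S matrix of optical-density stain vectors (columns);
#'   they are normalized to unit length and must be linearly independent.
#' @param od_threshold Optical density above which a pixel counts as
#'   positive in the collagen channel.
#' @param collagen Column index of the collagen stain.
#' @return A `stain_model` object.
#' @export
stain_model <- function(vectors, od_threshold = 0.15, collagen = 1L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3 || ncol(vectors) < 2 || ncol(vectors) > 3)
    stop("vectors must be a 3 x 2 or 3 x 3 matrix", call. = FALSE)
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm < 1e-9)) stop("zero stain vector", call. = FALSE)
  vectors <- sweep(vectors, 2, nrm, "/")
  if (qr(vectors)$rank < ncol(vectors))
    stop("singular stain matrix: stain vectors are linearly dependent", call. = FALSE)
  stopifnot_scalar_in(od_threshold, 1e-9, Inf, "od_threshold")
  structure(list(vectors = vectors, od_threshold = od_threshold,
                 collagen = as.integer(collagen)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>", ncol(x$vectors), "stains, collagen channel",
      x$collagen, "od_threshold", x$od_threshold, "\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' Published Masson-trichrome stain model
#'
#' Standard two-stain unmixing triplets for Masson's trichrome (aniline
#' blue collagen vs. acid fuchsin cytoplasm), completed with their cross
#' product as residual channel.  Stain vectors are lot-dependent; override
#' per batch where calibration is available.
#' @param od_threshold Positive-pixel threshold.
#' @return A [stain_model()] with the collagen stain in column 1.
#' @export
stain_model_masson <- function(od_threshold = 0.15) {
  collagen <- c(0.0999, 0.7374, 0.6680)   # aniline blue
  cyto     <- c(0.7995, 0.5913, 0.1053)   # fuchsin / ponceau
  third <- pracma_cross(collagen, cyto)
  stain_model(cbind(collagen, cyto, third), od_threshold, collagen = 1L)
}

#' Stain model matched to the synthetic generator's palette
#'
#' Optical-density vectors of the generator's collagen (blue-green) and
#' tissue (pink) reference colors, completed by their cross product.
#' @param od_threshold Positive-pixel threshold.
#' @return A [stain_model()] with the collagen stain in column 1.
#' @export
stain_model_synthetic <- function(od_threshold = 0.15) {
  od <- function(col) -log10((col * 255 + 1) / 256)
  collagen <- od(.hs_palette$collagen)
  cyto <- od(.hs_palette$tissue)
  stain_model(cbind(collagen, cyto, pracma_cross(collagen, cyto)),
              od_threshold, collagen = 1L)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Per-pixel optical density of an RGB image
#'
#' Beer-Lambert: `OD = -log10((I + 1) / 256)` per channel with `I` the 8-bit
#' intensity.
#' @param img RGB array in `[0, 1]`.
#' @return `npx x 3` matrix of optical densities.
#' @export
optical_density <- function(img) {
  I <- round(clamp(img, 0, 1) * 255)
  od <- -log10((I + 1) / 256)
  matrix(od, ncol = 3)
}

#' Unmix an image onto stain channels
#'
#' Least-squares projection of per-pixel optical density onto the stain
#' vectors.
#' @param img RGB array or [slide_image()].
#' @param sm A [stain_model()].
#' @return `npx x S` matrix of stain concentrations (OD units).
#' @export
stain_concentrations <- function(img, sm) {
  if (inherits(img, "slide_image")) img <- img$pixels
  stopifnot(inherits(sm, "stain_model"))
  od <- optical_density(img)
  M <- sm$vectors
  P <- solve(crossprod(M), t(M))          # S x 3 least-squares operator
  od %*% t(P)
}

#' Collagen area fraction by color deconvolution and thresholding
#'
#' @param img RGB array or [slide_image()].
#' @param sm A [stain_model()]; defaults to the synthetic-palette model.
#' @param sat_threshold Tissue saturation threshold (see
#'   [steatosis_area_fraction()]).
#' @return Collagen-positive pixels as percent of tissue pixels, or `NA`
#'   when no tissue is present.
#' @export
collagen_area_fraction <- function(img, sm = stain_model_synthetic(),
                                   sat_threshold = 0.08) {
  if (inherits(img, "slide_image")) img <- img$pixels
  conc <- stain_concentrations(img, sm)
  tissue <- tissue_vacuole_masks(img, sat_threshold, min_droplet_px = 0)$tissue
  n_tissue <- sum(tissue)
  if (n_tissue < 100) return(NA_real_)
  pos <- matrix(conc[, sm$collagen] > sm$od_threshold, nrow = nrow(tissue))
  100 * sum(pos & tissue) / n_tissue
}

#' Compare score groups against the control group
#'
#' Two-sample Wilcoxon rank-sum test of every group against the control
#' group, Holm-corrected across groups.  The control compared with itself is
#' reported as p = 1 by convention; groups of size < 2 are flagged and
#' untested.
#'
#' @param values Numeric measurements (e.g. collagen area or AI score).
#' @param groups Group labels (e.g. pathologist fibrosis scores).
#' @param control Label of the control group (default 0).
#' @return data.frame with group, n, median, effect direction, p, p_adj,
#'   flagged.
#' @export
group_comparison <- function(values, groups, control = 0) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  control <- as.character(control)
  if (!control %in% groups) stop("control group is empty", call. = FALSE)
  ctrl <- values[groups == control]
  lev <- unique(groups)
  lev <- c(control, sort(setdiff(lev, control)))
  if (length(lev) < 2) stop("need at least 2 groups", call. = FALSE)
  out <- do.call(rbind, lapply(lev, function(g) {
    v <- values[groups == g]
    flagged <- length(v) < 2
    if (g == control) {
      p <- 1; eff <- 0
    } else if (flagged) {
      p <- NA_real_; eff <- NA_real_
    } else {
      p <- stats::wilcox.test(v, ctrl, exact = FALSE)$p.value
      eff <- sign(stats::median(v) - stats::median(ctrl))
    }
    data.frame(group = g, n = length(v), median = stats::median(v),
               effect_dir = eff, p = p, flagged = flagged)
  }))
  idx <- out$group != control & !is.na(out$p)
  out$p_adj <- out$p
  out$p_adj[idx] <- stats::p.adjust(out$p[idx], method = "holm")
  out
}
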
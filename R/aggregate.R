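# Slide-level aggregation: one fixed-length feature vector per slide,
# consumed by the scoring network.  Three families: average renormalized
# class probabilities, average weighted class, and per-class spatial
# entropies of where each class's probability mass sits on the slide
# (low = focal, high = diffuse) — the spatial-pattern information a
# pathologist reads at a glance.

#' Normalized spatial entropy of one class over a feature map
#'
#' The class's ignore-renormalized probability mass over the T usable tiles
#' is normalized to a spatial distribution `q_t`; the entropy
#' `-sum(q_t log q_t) / log T` is 1 for mass spread uniformly over all
#' tiles and 0 for a point mass (and defined as 0 for T = 1 or zero total
#' mass).
#'
#' @param fm A `feature_map`.
#' @param class Class label or numeric class value.
#' @return Entropy in `[0, 1]`.
#' @export
class_entropy <- function(fm, class) {
  stopifnot(inherits(fm, "feature_map"))
  ci <- match(as.character(class), fm$labels[-length(fm$labels)])
  if (is.na(ci)) stop("unknown class: ", class, call. = FALSE)
  q <- usable_renormalized_probs(fm)[, ci]
  spatial_entropy(q)
}

spatial_entropy <- function(mass) {
  T <- length(mass)
  tot <- sum(mass)
  if (T <= 1 || tot <= 0) return(0)
  q <- mass / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(T)
}

# Renormalized numeric-class probabilities of the usable (non-ignore) tiles.
usable_renormalized_probs <- function(fm) {
  K <- length(fm$values)
  use <- !fm$ignore
  p <- fm$probs[use, seq_len(K), drop = FALSE]
  s <- rowSums(p)
  s[s <= 0] <- 1
  p / s
}

#' Aggregate a feature map to a slide feature vector
#'
#' Reduces the map to `2K + 1` numbers for K numeric classes: K average
#' renormalized class probabilities over the non-ignore tissue tiles, the
#' mean of the defined per-tile weighted scores, and K per-class spatial
#' entropies.  Invariant under any permutation of the tiles.
#'
#' @param fm A `feature_map`.
#' @return A `slide_features` object (or one flagged missing, with a
#'   warning, when no usable tile exists).  Slides with fewer than 5 usable
#'   tiles are flagged low-confidence.
#' @export
aggregate_feature_map <- function(fm) {
  stopifnot(inherits(fm, "feature_map"))
  K <- length(fm$values)
  use <- !fm$ignore
  n_used <- sum(use)
  if (n_used == 0) {
    warning("no usable tiles on slide ", fm$slide_id, "; flagged missing")
    return(structure(list(slide_id = fm$slide_id, feature = fm$feature, K = K,
                          avg_probs = rep(NA_real_, K), avg_weighted_class = NA_real_,
                          entropies = rep(NA_real_, K), n_tiles_used = 0L,
                          missing = TRUE, low_confidence = TRUE),
                     class = "slide_features"))
  }
  p <- usable_renormalized_probs(fm)
  avg_probs <- colMeans(p)
  ws <- map_weighted_scores(fm)
  avg_w <- mean(ws[!is.na(ws)])
  entropies <- vapply(seq_len(K), function(ci) spatial_entropy(p[, ci]), numeric(1))
  structure(list(slide_id = fm$slide_id, feature = fm$feature, K = K,
                 avg_probs = setNames(avg_probs, fm$labels[seq_len(K)]),
                 avg_weighted_class = avg_w,
                 entropies = setNames(entropies, fm$labels[seq_len(K)]),
                 n_tiles_used = as.integer(n_used),
                 missing = FALSE, low_confidence = n_used < 5),
            class = "slide_features")
}

#' @export
print.slide_features <- function(x, ...) {
  cat(sprintf("<slide_features> %s / %s: %d tiles used, avg weighted class %.3f%s\n",
              x$slide_id, x$feature, x$n_tiles_used, x$avg_weighted_class,
              if (isTRUE(x$low_confidence)) " [low confidence]" else ""))
  invisible(x)
}

#' Flatten slide features to the scoring-network input vector
#'
#' Layout: K average class probabilities, the average weighted class, K
#' entropies (length `2K + 1`).
#' @param sf A `slide_features` object.
#' @return Numeric vector of length `2K + 1`.
#' @export
as_ann_input <- function(sf) {
  stopifnot(inherits(sf, "slide_features"))
  c(sf$avg_probs, sf$avg_weighted_class, sf$entropies)
}

#' Append slide feature vectors to a cohort table
#'
#' @param sfs List of `slide_features`.
#' @return data.frame with slide_id, feature, n_tiles_used,
#'   avg_prob_0..K-1, avg_weighted, entropy_0..K-1.
#' @export
slide_features_table <- function(sfs) {
  do.call(rbind, lapply(sfs, function(sf) {
    K <- sf$K
    row <- data.frame(slide_id = sf$slide_id, feature = sf$feature,
                      n_tiles_used = sf$n_tiles_used)
    pr <- as.data.frame(t(sf$avg_probs)); names(pr) <- paste0("avg_prob_", seq_len(K) - 1)
    en <- as.data.frame(t(sf$entropies)); names(en) <- paste0("entropy_", seq_len(K) - 1)
    cbind(row, pr, avg_weighted = sf$avg_weighted_class, en)
  }))
}
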
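# Tile classification CNNs: one model per histological feature, each with
# the feature's ordinal classes plus one ignore class for artifacts and
# non-liver structure.  The concrete backbone is a small 4-conv-block
# network (3x3 conv / ReLU / 2x2 maxpool per block, global average pooling,
# softmax head) implemented in compiled code; tiles are bilinearly resized
# from 299 px to the backbone input size.

#' Specification of a tile classifier
#'
#' @param feature Histological feature; fixes the class scheme (ballooning
#'   0-1, inflammation 0-2, steatosis 5%-wide area bins, fibrosis 0-4) plus
#'   the ignore class, and the scale (fibrosis low, others high).
#' @param backbone `"small"` — the 4-conv-block backbone.  The large
#'   Inception-style backbone has no implementation in this package and is
#'   rejected with an explanatory error.
#' @param pretrained_mode `"none"`, `"imagenet"` or `"imagenet+domain"`.
#'   The non-none modes warm-start from a checkpoint passed to
#'   [train_classifier()] via `init_from`.
#' @param input_px Backbone input side (multiple of 16); defaults to 64 for
#'   steatosis (an area-fraction cue that survives coarse downscaling) and
#'   128 for the structure-sensitive features (ballooned single cells,
#'   lymphocyte clusters, perisinusoidal collagen texture).
#' @param channels Conv channels per block.
#' @param values Optional subset of the feature's class values (strictly
#'   increasing), e.g. a coarser selection of steatosis bins for desk-scale
#'   experiments; default all.
#' @param pool Global pooling of the final stage feeding the head:
#'   `"avg"` (density-like classes) or `"max"` (presence classes; default
#'   for ballooning).
#' @return A `classifier_spec` object with `labels` (character class labels,
#'   ignore last), `values` (numeric class values) and geometry fields.
#' @export
classifier_spec <- function(feature,
                            backbone = c("small", "inception_v3"),
                            pretrained_mode = c("none", "imagenet", "imagenet+domain"),
                            input_px = NULL, channels = c(8L, 16L, 32L, 32L),
                            values = NULL, pool = NULL) {
  feature <- match_feature(feature)
  input_px <- input_px %||% (if (feature == "steatosis") 64L else 128L)
  # structure-presence classes need a max-pooled head: average pooling
  # dilutes one small ballooned cell (or a sparse perisinusoidal patch)
  # over the whole tile; fibrosis staging is "the strongest structure
  # present" (rings > bridges > rims > pericellular wire > specks)
  if (is.null(pool)) pool <- if (feature %in% c("ballooning", "fibrosis")) "max" else "avg"
  pool <- match.arg(pool, c("avg", "max"))
  backbone <- match.arg(backbone)
  pretrained_mode <- match.arg(pretrained_mode)
  if (backbone == "inception_v3")
    stop("no Inception-V3 implementation is available in this package; ",
         "use backbone = \"small\"", call. = FALSE)
  if (input_px %% 2^length(channels) != 0)
    stop("input_px must be divisible by 2^", length(channels), call. = FALSE)
  all_values <- valid_tile_classes(feature)
  if (is.null(values)) values <- all_values
  values <- sort(unique(as.integer(values)))
  if (!all(values %in% all_values))
    stop("invalid class values for ", feature, call. = FALSE)
  structure(list(feature = feature,
                 scale = if (feature == "fibrosis") "low" else "high",
                 tile_px = .hs_geometry$tile_px,
                 values = as.numeric(values),
                 labels = c(as.character(values), "ignore"),
                 n_classes = length(values) + 1L,
                 backbone = backbone,
                 pretrained_mode = pretrained_mode,
                 input_px = as.integer(input_px),
                 channels = as.integer(channels),
                 pool = pool),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (%s scale): %d classes + ignore, %s backbone %dpx\n",
              x$feature, x$scale, x$n_classes - 1L, x$backbone, x$input_px))
  invisible(x)
}

#' Stratified train/validation split of labeled tiles
#'
#' Splits per class; the overall validation size is exactly
#' `round(n * (1 - train_frac))`, allocated across classes by largest
#' remainder.  Classes with fewer than 2 tiles stay whole in the training
#' set with a warning.
#'
#' @param labels Class label per tile (character or factor).
#' @param train_frac Training fraction, default 0.95.
#' @param seed Integer seed; the partition is reproducible.
#' @return list with integer index vectors `train` and `val` (disjoint,
#'   exhaustive).
#' @export
split_tiles <- function(labels, train_frac = 0.95, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1) stop("no tiles", call. = FALSE)
  stopifnot_scalar_in(train_frac, 0, 1, "train_frac")
  n_val <- round(n * (1 - train_frac))
  if (n_val == 0) warning("empty validation set (train_frac = ", train_frac, ")")
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  if (length(small))
    warning("class(es) with < 2 tiles kept whole in training: ",
            paste(small, collapse = ", "))
  eligible <- setdiff(names(counts), small)
  quota <- setNames(rep(0L, length(counts)), names(counts))
  if (length(eligible) && n_val > 0) {
    q <- counts[eligible] * (1 - train_frac)
    base <- pmin(floor(q), counts[eligible] - 1L)
    rem <- n_val - sum(base)
    if (rem > 0) {
      frac <- q - floor(q)
      room <- counts[eligible] - 1L - base
      ord <- order(frac, decreasing = TRUE)
      for (i in ord) {
        if (rem <= 0) break
        add <- min(room[i], rem)
        if (add > 0) { base[i] <- base[i] + add; rem <- rem - add }
      }
    } else if (rem < 0) {
      ord <- order(q - floor(q))
      for (i in ord) {
        if (rem >= 0) break
        take <- min(base[i], -rem)
        base[i] <- base[i] - take; rem <- rem + take
      }
    }
    quota[eligible] <- as.integer(base)
  }
  with_seed(seed, {
    val <- integer(0)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      k <- quota[[cl]]
      if (k > 0) val <- c(val, sample(idx, k))
    }
    val <- sort(val)
    list(train = setdiff(seq_len(n), val), val = val)
  })
}

init_cnn_weights <- function(spec, seed = 1L) {
  with_seed(seed, {
    ch <- c(3L, spec$channels)
    conv <- lapply(seq_along(spec$channels), function(l) {
      din <- 9L * ch[l]
      list(W = matrix(rnorm(din * ch[l + 1], sd = sqrt(2 / din)), din, ch[l + 1]),
           b = rep(0, ch[l + 1]))
    })
    clast <- ch[length(ch)]
    list(conv = conv,
         fc = list(W = matrix(rnorm(clast * spec$n_classes, sd = sqrt(2 / clast)),
                              clast, spec$n_classes),
                   b = rep(0, spec$n_classes)))
  })
}

zeros_like_weights <- function(w) rapply(w, function(x) x * 0, how = "replace")

pool_flag <- function(spec) if (identical(spec$pool, "max")) 1L else 0L

# Downscale one tile to the backbone input by exact area averaging over the
# full tile (no cropping: objects at tile borders must stay visible), on the
# identical deterministic path at training and inference.
tile_to_input <- function(tile, input_px) {
  d <- dim(tile)
  if (d[1] == input_px && d[2] == input_px) return(tile)
  cpp_resize_area(tile, input_px, input_px)
}

# Coerce tiles to the stacked input array (input_px, input_px, 3, N).
as_input_array <- function(x, spec) {
  if (is.array(x) && length(dim(x)) == 4) {
    if (dim(x)[1] != spec$input_px || dim(x)[2] != spec$input_px)
      stop("4d tile array must already be at input_px", call. = FALSE)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3) x <- list(x)
  n <- length(x)
  out <- array(0, c(spec$input_px, spec$input_px, 3, n))
  for (i in seq_len(n)) {
    ti <- x[[i]]
    d <- dim(ti)
    if (length(d) != 3 || d[3] != 3 || d[1] != spec$tile_px || d[2] != spec$tile_px)
      stop("tile ", i, " is not a ", spec$tile_px, " px RGB tile", call. = FALSE)
    out[, , , i] <- tile_to_input(ti, spec$input_px)
  }
  out
}

labels_to_index <- function(y, spec) {
  idx <- match(as.character(y), spec$labels)
  if (anyNA(idx))
    stop("unknown class label(s): ",
         paste(unique(as.character(y)[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

# Random dihedral-group augmentation (flips + 90-degree rotations); histology
# has no canonical orientation.
augment_batch <- function(X, seed_draws) {
  n <- dim(X)[4]
  for (i in seq_len(n)) {
    k <- seed_draws[i]
    xi <- X[, , , i]
    if (bitwAnd(k, 1L)) xi <- xi[rev(seq_len(dim(xi)[1])), , , drop = FALSE]
    if (bitwAnd(k, 2L)) xi <- xi[, rev(seq_len(dim(xi)[2])), , drop = FALSE]
    if (bitwAnd(k, 4L)) xi <- aperm(xi, c(2, 1, 3))
    X[, , , i] <- xi
  }
  X
}

#' Train a tile classification CNN
#'
#' Minibatch Adam on cross-entropy with per-class weighted sampling (skewed
#' annotation counts are the norm), flip/rotation augmentation, and
#' per-epoch learning curves on the training and validation sets.
#'
#' @param spec A [classifier_spec()].
#' @param train,val Lists with `x` (list of 299 px tiles, or a
#'   `input_px^2 x 3 x N` array already resized) and `y` (class labels).
#'   `val` may be NULL.
#' @param epochs Training epochs; 0 returns the initialized model with an
#'   empty history.
#' @param seed Integer seed; training is deterministic given data and seed.
#' @param lr,batch Adam learning rate and minibatch size.
#' @param augment Apply flip/rotation augmentation.
#' @param balanced Per-class weighted sampling of the training order.
#' @param init_from Path to a checkpoint (a saved `tile_cnn`) used to
#'   warm-start when `spec$pretrained_mode` is not `"none"`: mode
#'   `"imagenet"` copies the convolutional backbone only, mode
#'   `"imagenet+domain"` also copies a shape-compatible head.
#' @param keep_best Return the weights of the epoch with the highest
#'   validation accuracy (the learning curves plateau with late-epoch
#'   wobble; the plateau model, not the last minibatch, is the model).
#'   Requires a validation set; otherwise the final weights are kept.
#' @return A `tile_cnn` model with `history` (per-epoch data.frame) and
#'   `confusion` (validation confusion matrix, truth in rows).
#' @export
train_classifier <- function(spec, train, val = NULL, epochs = 10L, seed = 1L,
                             lr = 1e-3, batch = 32L, augment = TRUE,
                             balanced = TRUE, init_from = NULL,
                             keep_best = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as_input_array(train$x, spec)
  y <- labels_to_index(train$y, spec)
  present <- sort(unique(y))
  missing_cls <- setdiff(seq_len(spec$n_classes), present)
  if (length(missing_cls) == spec$n_classes)
    stop("empty training set", call. = FALSE)
  if (length(missing_cls))
    stop("class(es) absent from training set: ",
         paste(spec$labels[missing_cls], collapse = ", "), call. = FALSE)
  if (spec$pretrained_mode != "none" && is.null(init_from))
    stop("pretrained_mode '", spec$pretrained_mode, "' requires init_from: ",
         "no pretrained weights ship with this package", call. = FALSE)

  weights <- init_cnn_weights(spec, seed)
  if (!is.null(init_from)) {
    prior <- if (inherits(init_from, "tile_cnn")) init_from else load_classifier(init_from)
    for (l in seq_along(weights$conv)) {
      if (!identical(dim(prior$weights$conv[[l]]$W), dim(weights$conv[[l]]$W)))
        stop("checkpoint backbone shape mismatch at conv block ", l, call. = FALSE)
      weights$conv[[l]] <- prior$weights$conv[[l]]
    }
    if (spec$pretrained_mode == "imagenet+domain" &&
        identical(dim(prior$weights$fc$W), dim(weights$fc$W)))
      weights$fc <- prior$weights$fc
  }

  Xv <- NULL; yv <- NULL
  if (!is.null(val) && length(val$y)) {
    Xv <- as_input_array(val$x, spec)
    yv <- labels_to_index(val$y, spec)
  }
  m <- zeros_like_weights(weights); v <- zeros_like_weights(weights); t <- 0
  hist <- vector("list", epochs)
  best <- list(acc = -Inf, weights = weights, epoch = 0L)
  n <- length(y)
  counts <- tabulate(y, spec$n_classes)
  w_sample <- if (balanced) 1 / counts[y] else rep(1, n)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n, n, replace = balanced, prob = if (balanced) w_sample else NULL)
      Xe <- if (augment) augment_batch(X, sample.int(8L, n, replace = TRUE) - 1L) else X
      r <- cpp_cnn_train_epoch(weights, m, v, t, Xe, as.integer(y - 1L),
                               as.integer(ord - 1L), as.integer(batch),
                               lr, 0.9, 0.999, 1e-8, pool_flag(spec))
      weights <- r$weights; m <- r$m; v <- r$v; t <- r$t
      row <- data.frame(epoch = ep, train_loss = r$loss, train_acc = r$acc,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(Xv)) {
        pv <- cpp_cnn_predict(weights, Xv, pool_flag(spec))
        row$val_loss <- mean(-log(pmax(pv[cbind(seq_along(yv), yv)], 1e-12)))
        row$val_acc <- mean(max.col(pv) == yv)
        if (keep_best && row$val_acc >= best$acc)
          best <- list(acc = row$val_acc, weights = weights, epoch = ep)
      }
      hist[[ep]] <- row
    }
  })
  history <- if (epochs > 0) do.call(rbind, hist) else
    data.frame(epoch = integer(0), train_loss = numeric(0), train_acc = numeric(0),
               val_loss = numeric(0), val_acc = numeric(0))
  best_epoch <- epochs
  if (keep_best && !is.null(Xv) && best$epoch > 0) {
    weights <- best$weights
    best_epoch <- best$epoch
  }
  confusion <- NULL
  if (!is.null(Xv)) {
    pv <- cpp_cnn_predict(weights, Xv, pool_flag(spec))
    confusion <- table(truth = factor(spec$labels[yv], levels = spec$labels),
                       pred = factor(spec$labels[max.col(pv)], levels = spec$labels))
  }
  structure(list(spec = spec, weights = weights, history = history,
                 confusion = confusion, epochs = epochs, best_epoch = best_epoch,
                 seed = seed),
            class = "tile_cnn")
}

#' @export
print.tile_cnn <- function(x, ...) {
  va <- if (nrow(x$history)) x$history$val_acc[nrow(x$history)] else NA
  cat(sprintf("<tile_cnn> %s (%s scale), %d classes, %d epochs%s\n",
              x$spec$feature, x$spec$scale, x$spec$n_classes, x$epochs,
              if (is.finite(va)) sprintf(", val acc %.3f", va) else ""))
  invisible(x)
}

#' Classify tiles with a trained model
#'
#' @param model A `tile_cnn`.
#' @param tiles One tile (299 px RGB array), a list of tiles, or a
#'   pre-resized `input_px^2 x 3 x N` array.
#' @return `N x K` matrix of class probabilities (columns named by class
#'   labels, ignore last), rows summing to 1, order-preserving.
#' @export
classify_tiles <- function(model, tiles) {
  UseMethod("classify_tiles")
}

#' @export
classify_tiles.tile_cnn <- function(model, tiles) {
  X <- as_input_array(tiles, model$spec)
  p <- cpp_cnn_predict(model$weights, X, pool_flag(model$spec))
  colnames(p) <- model$spec$labels
  p
}

#' @rdname classify_tiles
#' @export
classify_tile <- function(model, tiles) {
  p <- classify_tiles(model, tiles)
  stats::setNames(p[1, ], colnames(p))
}

#' Class activation map of one tile
#'
#' Gradient-weighted activation of the final convolutional stage for the
#' target class: with global average pooling feeding the softmax head, the
#' gradient of the class logit with respect to channel k of the final stage
#' is the head weight, so the map is `relu(sum_k w_kc A_k)`, bilinearly
#' upsampled to the tile and min-max normalized (a constant map normalizes
#' to all zeros).
#'
#' @param model A `tile_cnn`.
#' @param tile A 299 px RGB tile (or pre-resized input array).
#' @param target_class Class label (e.g. `"3"` or `"ignore"`).
#' @return list with `map` (tile-sized matrix in `[0, 1]`) and `confidence`
#'   (the model's probability for the target class).
#' @export
class_activation_map <- function(model, tile, target_class) {
  stopifnot(inherits(model, "tile_cnn"))
  ci <- match(as.character(target_class), model$spec$labels)
  if (is.na(ci)) stop("unknown class: ", target_class, call. = FALSE)
  out_px <- if (is.array(tile) && length(dim(tile)) == 3) dim(tile)[1] else model$spec$tile_px
  X <- as_input_array(tile, model$spec)
  r <- cpp_cnn_features(model$weights, X, pool_flag(model$spec))
  A <- r$features[, , , 1]
  w <- model$weights$fc$W[, ci]
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) cam <- cam + w[k] * A[, , k]
  cam[cam < 0] <- 0
  rng <- range(cam)
  cam <- if (diff(rng) < 1e-12) matrix(0, nrow(cam), ncol(cam))
         else (cam - rng[1]) / diff(rng)
  up <- EBImage::resize(EBImage::Image(t(cam)), w = out_px, h = out_px)
  map <- t(EBImage::imageData(up))
  map <- clamp(map, 0, 1)
  list(map = map, confidence = unname(r$probs[1, ci]))
}

#' Save / load a tile classifier checkpoint
#'
#' The checkpoint embeds the spec, so a loaded model is self-describing.
#' @param model A `tile_cnn`.
#' @param path Checkpoint path (.rds).
#' @return `path` / the `tile_cnn`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "tile_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tile_cnn")) stop("not a tile_cnn checkpoint", call. = FALSE)
  model
}

# Weight checksum used in determinism checks.
weights_checksum <- function(model) {
  sum(unlist(rapply(model$weights, function(x) sum(x * seq_along(x)), how = "unlist")))
}
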
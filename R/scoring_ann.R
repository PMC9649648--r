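# Per-feature scoring networks: small feedforward regressors (two hidden
# layers) mapping slide feature vectors to continuous scores.  A scaled
# logistic output activation confines every prediction to the pathologist's
# score range; training minimizes the MSE against the discrete ground-truth
# scores with slide-level stratified cross-validation.

#' Range-bounding output activation
#'
#' `s_max * plogis(z)`: strictly increasing, with limits 0 and `s_max`, and
#' midpoint `s_max / 2` at z = 0.
#' @param z Real pre-activation(s).
#' @param s_max Upper bound of the score range (> 0).
#' @return Values in `(0, s_max)`.
#' @export
bounded_activation <- function(z, s_max) {
  stopifnot_scalar_in(s_max, 1e-12, Inf, "s_max")
  s_max * stats::plogis(z)
}

init_mlp <- function(d, hidden, seed) {
  with_seed(seed, {
    h1 <- hidden[1]; h2 <- hidden[2]
    list(W1 = matrix(rnorm(d * h1, sd = sqrt(2 / d)), d, h1), b1 = rep(0, h1),
         W2 = matrix(rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2), b2 = rep(0, h2),
         w3 = rnorm(h2, sd = sqrt(1 / h2)), b3 = 0)
  })
}

mlp_forward <- function(w, X) {
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+"); A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% w$W2, 2, w$b2, "+"); A2 <- pmax(Z2, 0)
  z3 <- as.vector(A2 %*% w$w3) + w$b3
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, z3 = z3)
}

#' Fit a bounded-output scoring network
#'
#' Full-batch Adam on the MSE between the bounded continuous output and the
#' discrete truth.  Deterministic for a fixed seed.
#'
#' @param X `n x d` input matrix (slide feature vectors).
#' @param y Numeric truth scores in `[0, s_max]`.
#' @param s_max Score range upper bound.
#' @param hidden Hidden-layer widths, default `c(16, 8)`.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @return A `scoring_ann` model with the per-epoch MSE learning `curve`.
#' @export
fit_scoring_ann <- function(X, y, s_max, hidden = c(16L, 8L), epochs = 400L,
                            lr = 0.01, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(hidden) == 2)
  if (any(y < 0 | y > s_max)) stop("truth scores outside [0, s_max]", call. = FALSE)
  w <- init_mlp(ncol(X), hidden, seed)
  m <- rapply(w, function(x) x * 0, how = "replace")
  v <- m
  n <- nrow(X)
  curve <- numeric(epochs)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    f <- mlp_forward(w, X)
    sig <- stats::plogis(f$z3)
    yhat <- s_max * sig
    err <- yhat - y
    curve[t] <- mean(err^2)
    dz3 <- (2 / n) * err * s_max * sig * (1 - sig)
    g <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
              w3 = as.vector(t(f$A2) %*% dz3), b3 = sum(dz3))
    dA2 <- outer(dz3, w$w3)
    dZ2 <- dA2 * (f$Z2 > 0)
    g$W2 <- t(f$A1) %*% dZ2; g$b2 <- colSums(dZ2)
    dA1 <- dZ2 %*% t(w$W2)
    dZ1 <- dA1 * (f$Z1 > 0)
    g$W1 <- t(X) %*% dZ1; g$b1 <- colSums(dZ1)
    for (nm in names(w)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mh <- m[[nm]] / (1 - b1^t); vh <- v[[nm]] / (1 - b2^t)
      w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  structure(list(weights = w, s_max = s_max, d = ncol(X), hidden = hidden,
                 curve = curve, epochs = epochs, seed = seed),
            class = "scoring_ann")
}

#' @export
print.scoring_ann <- function(x, ...) {
  cat(sprintf("<scoring_ann> %d -> %d -> %d -> 1, range [0, %g], final MSE %.4f\n",
              x$d, x$hidden[1], x$hidden[2], x$s_max,
              if (length(x$curve)) x$curve[length(x$curve)] else NA))
  invisible(x)
}

#' @export
predict.scoring_ann <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "slide_features")) matrix(as_ann_input(newdata), 1)
       else as.matrix(newdata)
  if (ncol(X) != object$d)
    stop("input dimension ", ncol(X), " does not match model (", object$d, ")",
         call. = FALSE)
  f <- mlp_forward(object$weights, X)
  bounded_activation(f$z3, object$s_max)
}

#' Continuous score of one slide
#' @param model A `scoring_ann`.
#' @param v A `slide_features` object or input vector.
#' @return Score in `[0, s_max]`.
#' @export
predict_score <- function(model, v) {
  if (inherits(v, "slide_features")) v <- as_ann_input(v)
  as.numeric(predict(model, matrix(v, 1)))
}

# Stratified fold assignment: members of each truth level are dealt
# round-robin into folds with a rotating offset, so small score classes
# appear in all folds wherever possible.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    off <- 0
    for (lev in sort(unique(y))) {
      idx <- sample(which(y == lev))
      fold[idx] <- ((seq_along(idx) - 1 + off) %% folds) + 1
      off <- off + length(idx)
    }
    fold
  })
}

#' Train a scoring network with slide-level cross-validation
#'
#' Slides (not tiles) are partitioned into folds stratified by the truth
#' score; each fold's model is fit on the remaining folds and predicts the
#' held-out slides, so every scored slide receives exactly one out-of-fold
#' prediction.  Slides with missing truth are excluded.
#'
#' @param features `n x d` matrix of slide feature vectors (or list of
#'   `slide_features`).
#' @param truth Integer pathologist scores (NA = missing).
#' @param feature Feature name; fixes the score range.
#' @param folds Number of CV folds, default 4.
#' @param seed Integer seed (fold assignment and fits are reproducible).
#' @param slide_ids Optional slide identifiers for the records.
#' @param hidden,epochs,lr Passed to [fit_scoring_ann()].
#' @return list with `models` (per fold), `records` (data.frame slide_id,
#'   feature, truth, ai_score, fold — out-of-fold predictions), `curves`
#'   (per-fold learning curves) and `fold_of` (fold assignment).
#' @export
train_scoring_ann <- function(features, truth, feature, folds = 4L, seed = 1L,
                              slide_ids = NULL, hidden = c(16L, 8L),
                              epochs = 400L, lr = 0.01) {
  feature <- if (feature == "nas") "nas" else match_feature(feature)
  s_max <- if (feature == "nas") 8 else score_range(feature)
  if (is.list(features) && !is.matrix(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, as_ann_input))
  X <- as.matrix(features)
  slide_ids <- slide_ids %||% rownames(X) %||% sprintf("slide%04d", seq_len(nrow(X)))
  bad_rows <- rowSums(is.na(X)) > 0
  if (any(bad_rows))
    warning(sum(bad_rows), " slide(s) with missing feature vectors excluded")
  keep <- which(!is.na(truth) & !bad_rows)
  if (length(keep) < folds)
    stop("need at least ", folds, " slides with non-missing truth", call. = FALSE)
  Xk <- X[keep, , drop = FALSE]; yk <- truth[keep]; ids <- slide_ids[keep]
  fold <- stratified_folds(yk, folds, seed)
  if (length(unique(fold)) < folds)
    warning("some folds are empty; stratification is best-effort")
  for (f in seq_len(folds)) {
    lost <- setdiff(unique(yk), unique(yk[fold != f]))
    if (length(lost))
      warning("fold ", f, " training set misses score level(s) ",
              paste(lost, collapse = ", "), "; proceeding")
  }
  models <- vector("list", folds); curves <- vector("list", folds)
  pred <- rep(NA_real_, length(yk))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (!any(tr) || !any(!tr)) next
    models[[f]] <- fit_scoring_ann(Xk[tr, , drop = FALSE], yk[tr], s_max,
                                   hidden = hidden, epochs = epochs, lr = lr,
                                   seed = child_seed(seed, f))
    curves[[f]] <- models[[f]]$curve
    pred[!tr] <- predict(models[[f]], Xk[!tr, , drop = FALSE])
  }
  records <- data.frame(slide_id = ids, feature = feature, truth = yk,
                        ai_score = pred, fold = fold, stringsAsFactors = FALSE)
  list(models = models, records = records, curves = curves,
       fold_of = setNames(fold, ids))
}

#' NAFLD activity score from component scores
#'
#' The sum of the steatosis, inflammation and ballooning scores, on
#' `[0, 8]`; components must lie within their own ranges.
#'
#' @param steatosis Score(s) in `[0, 3]`.
#' @param inflammation Score(s) in `[0, 3]`.
#' @param ballooning Score(s) in `[0, 2]`.
#' @return Numeric NAS value(s).
#' @export
nas <- function(steatosis, inflammation, ballooning) {
  if (any(steatosis < 0 | steatosis > 3, na.rm = TRUE))
    stop("steatosis score out of [0, 3]", call. = FALSE)
  if (any(inflammation < 0 | inflammation > 3, na.rm = TRUE))
    stop("inflammation score out of [0, 3]", call. = FALSE)
  if (any(ballooning < 0 | ballooning > 2, na.rm = TRUE))
    stop("ballooning score out of [0, 2]", call. = FALSE)
  steatosis + inflammation + ballooning
}
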
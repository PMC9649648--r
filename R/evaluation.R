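# Ordinal agreement metrics between continuous AI scores and discrete
# pathologist scores: MAE on the continuous predictions; quadratic weighted
# Cohen's kappa and support-weighted precision/recall/F1 on the discretized
# predictions.

#' Discretize a continuous score
#'
#' Round half up to the nearest integer, clipped to `[0, s_max]`.
#' @param ai_score Continuous score(s).
#' @param s_max Upper bound of the scale.
#' @return Integer score(s).
#' @export
discretize_score <- function(ai_score, s_max) {
  as.integer(clamp(floor(ai_score + 0.5), 0, s_max))
}

#' Mean absolute error
#'
#' Computed on the continuous predictions (not discretized); pairs with
#' missing truth are excluded.
#' @param predictions Continuous predictions.
#' @param truth Discrete truth scores (NA allowed).
#' @return MAE.
#' @export
score_mae <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  keep <- !is.na(truth) & !is.na(predictions)
  if (!any(keep)) stop("no scored pairs", call. = FALSE)
  mean(abs(predictions[keep] - truth[keep]))
}

#' Quadratic weighted Cohen's kappa
#'
#' Chance-corrected agreement penalizing disagreements by squared level
#' distance: `kappa = 1 - sum(w * O) / sum(w * E)` with
#' `w_ij = (i - j)^2 / S^2`, observed counts O and expected counts E from
#' the outer product of the marginals scaled to n.  When both raters are
#' constant and equal (zero expected disagreement), kappa is defined as 1.
#'
#' @param pred Discrete predictions within `levels`.
#' @param truth Discrete truth within `levels`.
#' @param levels Ordered level vector, default `0:max(s)`.
#' @return Kappa in `[-1, 1]`.
#' @export
quadratic_weighted_kappa <- function(pred, truth, levels = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  levels <- levels %||% seq(0, max(pred, truth))
  if (!all(pred %in% levels) || !all(truth %in% levels))
    stop("values outside the level set", call. = FALSE)
  K <- length(levels)
  O <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  W <- outer(seq_len(K) - 1, seq_len(K) - 1, function(i, j) (i - j)^2) / (K - 1)^2
  denom <- sum(W * E)
  if (denom == 0) return(1)
  1 - sum(W * O) / denom
}

#' Support-weighted precision, recall and F1
#'
#' Per-level one-vs-rest precision/recall/F1 averaged with weights equal to
#' the level's support in the truth; levels absent from the truth carry
#' zero weight, and per-level zero divisions resolve to 0.
#'
#' @param pred Discrete predictions.
#' @param truth Discrete truth.
#' @param levels Ordered level vector.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
weighted_prf <- function(pred, truth, levels = NULL) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  levels <- levels %||% seq(0, max(pred, truth))
  n <- length(truth)
  prec <- rec <- f1 <- w <- numeric(length(levels))
  for (i in seq_along(levels)) {
    l <- levels[i]
    tp <- sum(pred == l & truth == l)
    fp <- sum(pred == l & truth != l)
    fn <- sum(pred != l & truth == l)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    w[i] <- sum(truth == l) / n
  }
  c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Evaluate score records per feature (plus NAS)
#'
#' Builds one evaluation row per feature from out-of-fold or test-set score
#' records: n, MAE (continuous), quadratic weighted kappa,
#' support-weighted precision/recall/F1 (both on rounded predictions), and
#' the confusion matrix.  A NAS row is added when all three active-injury
#' features are present: truth NAS is the sum of the discrete component
#' truths, AI NAS the sum of the continuous component scores, discretized
#' to 0-8 for the categorical metrics.
#'
#' @param records data.frame with columns slide_id, feature, truth,
#'   ai_score (rows with missing truth are excluded per feature).
#' @param dataset Dataset label for the report.
#' @return An `eval_report`: data.frame (one row per feature, Table-style
#'   column order) with the confusion matrices in `attr(, "confusion")`.
#' @export
evaluate_scores <- function(records, dataset = "synthetic") {
  stopifnot(all(c("slide_id", "feature", "truth", "ai_score") %in% names(records)))
  feats <- intersect(c(hs_features(), "nas"), unique(records$feature))
  if ("nas" %in% records$feature) feats <- union(feats, "nas")
  nas_parts <- c("steatosis", "inflammation", "ballooning")
  if (all(nas_parts %in% feats) && !"nas" %in% feats) {
    wide_t <- wide_s <- NULL
    for (f in nas_parts) {
      r <- records[records$feature == f & !is.na(records$truth), ]
      m <- r[, c("slide_id", "truth", "ai_score")]
      names(m)[2:3] <- paste0(c("t_", "s_"), f)
      wide_t <- if (is.null(wide_t)) m else merge(wide_t, m, by = "slide_id")
    }
    if (!is.null(wide_t) && nrow(wide_t)) {
      nas_rec <- data.frame(slide_id = wide_t$slide_id, feature = "nas",
                            truth = wide_t$t_steatosis + wide_t$t_inflammation + wide_t$t_ballooning,
                            ai_score = wide_t$s_steatosis + wide_t$s_inflammation + wide_t$s_ballooning)
      records <- rbind(records[, c("slide_id", "feature", "truth", "ai_score")], nas_rec)
      feats <- c(feats, "nas")
    }
  }
  rows <- list(); confs <- list()
  for (f in feats) {
    r <- records[records$feature == f & !is.na(records$truth) & !is.na(records$ai_score), ]
    if (!nrow(r)) { warning("no records for feature ", f, "; omitted"); next }
    s_max <- if (f == "nas") 8L else score_range(f)
    levels <- 0:s_max
    pd <- discretize_score(r$ai_score, s_max)
    prf <- weighted_prf(pd, r$truth, levels)
    rows[[f]] <- data.frame(
      score = f, dataset = dataset,
      mae = score_mae(r$ai_score, r$truth),
      kappa_qw = quadratic_weighted_kappa(pd, r$truth, levels),
      weighted_precision = prf[["precision"]],
      weighted_recall = prf[["recall"]],
      weighted_f1 = prf[["f1"]],
      n = nrow(r))
    confs[[f]] <- table(truth = factor(r$truth, levels = levels),
                        pred = factor(pd, levels = levels))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, confusion = confs, class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n"
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report (and confusion matrices) to CSV
#' @param report An `eval_report`.
#' @param path Report CSV path; confusions go to `<path>_confusion_<feature>.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  confs <- attr(report, "confusion")
  base <- sub("\\.csv$", "", path)
  for (f in names(confs))
    write.csv(as.data.frame.matrix(confs[[f]]),
              paste0(base, "_confusion_", f, ".csv"))
  invisible(path)
}
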
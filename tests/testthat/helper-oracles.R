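# Independent brute-force oracles, deliberately written from first
# principles (explicit loops and double sums) so they share no code with the
# package implementations they check.

# Quadratic weighted Cohen's kappa from the definition: observed and
# expected matrices and the explicit double sum over rater-pair cells.
oracle_qwk <- function(pred, truth, levels) {
  K <- length(levels)
  n <- length(pred)
  O <- matrix(0, K, K)
  for (a in seq_len(n)) {
    i <- which(levels == truth[a]); j <- which(levels == pred[a])
    O[i, j] <- O[i, j] + 1
  }
  E <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    E[i, j] <- sum(O[i, ]) * sum(O[, j]) / n
  num <- 0; den <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w <- (i - j)^2
    num <- num + w * O[i, j]
    den <- den + w * E[i, j]
  }
  if (den == 0) return(1)
  1 - num / den
}

# Support-weighted precision/recall/F1 from explicit per-class counting.
oracle_prf <- function(pred, truth, levels) {
  p_sum <- r_sum <- f_sum <- 0
  n <- length(truth)
  for (l in levels) {
    tp <- 0; fp <- 0; fn <- 0
    for (a in seq_len(n)) {
      if (pred[a] == l && truth[a] == l) tp <- tp + 1
      if (pred[a] == l && truth[a] != l) fp <- fp + 1
      if (pred[a] != l && truth[a] == l) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    w <- (tp + fn) / n
    p_sum <- p_sum + w * prec; r_sum <- r_sum + w * rec; f_sum <- f_sum + w * f1
  }
  c(precision = p_sum, recall = r_sum, f1 = f_sum)
}

# Random valid feature map: n tiles over K numeric classes + ignore.
random_feature_map <- function(rows, cols, K = 5, seed = 1, p_skip = 0,
                               ignore_scale = 0.2) {
  set.seed(seed)
  n <- rows * cols
  probs <- matrix(0, n, K + 1)
  for (i in seq_len(n)) {
    raw <- c(rexp(K), rexp(1) * ignore_scale)
    probs[i, ] <- raw / sum(raw)
  }
  if (p_skip > 0) {
    skip <- runif(n) < p_skip
    probs[skip, ] <- NA
  }
  feature_map(probs, values = 0:(K - 1), rows = rows, cols = cols)
}

spearman <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))
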
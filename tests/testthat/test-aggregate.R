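one_hot_map <- function(class, rows, cols, K = 5) {
  n <- rows * cols
  probs <- matrix(0, n, K + 1)
  probs[, class + 1] <- 1
  feature_map(probs, 0:(K - 1), rows, cols)
}

test_that("uniform one-hot maps give unit entropy and exact averages", {
  fm <- one_hot_map(2, 4, 4)
  sf <- aggregate_feature_map(fm)
  expect_equal(unname(sf$avg_probs), c(0, 0, 1, 0, 0))
  expect_equal(sf$avg_weighted_class, 2)
  expect_equal(class_entropy(fm, 2), 1)         # mass spread over all tiles
  expect_equal(sf$n_tiles_used, 16L)
})

test_that("point-mass spatial distributions have zero entropy", {
  n <- 16; K <- 5
  probs <- matrix(0, n, K + 1)
  probs[, 1] <- 1                                # background class 0
  probs[5, ] <- 0; probs[5, 4] <- 1              # all class-3 mass in one tile
  fm <- feature_map(probs, 0:4, 4, 4)
  expect_equal(class_entropy(fm, 3), 0)
  # class 0 spread uniformly over the other 15 of 16 tiles
  expect_equal(class_entropy(fm, 0), log(15) / log(16))
})

test_that("half-half mass over four tiles gives entropy one half", {
  probs <- matrix(0, 4, 3)
  probs[1, ] <- c(0, 1, 0); probs[2, ] <- c(0, 1, 0)
  probs[3, ] <- c(1, 0, 0); probs[4, ] <- c(1, 0, 0)
  fm <- feature_map(probs, 0:1, 2, 2)
  # class 1 mass: (1, 1, 0, 0) over 4 tiles -> ln2 / ln4 = 0.5
  expect_equal(class_entropy(fm, 1), 0.5)
})

test_that("aggregation equals a brute-force recomputation from the CSV export", {
  fm <- random_feature_map(10, 10, K = 5, seed = 13, ignore_scale = 0.3)
  sf <- aggregate_feature_map(fm)
  path <- tempfile()
  export_feature_map(fm, path)
  df <- read.csv(paste0(path, ".csv"))
  # brute force from the exported rows, written independently
  pc <- as.matrix(df[, paste0("p_", 0:4)])
  pig <- df$p_ignore
  usable <- !is.na(pig) & max.col(cbind(pc, pig)) != 6
  ren <- pc[usable, ] / rowSums(pc[usable, ])
  expect_equal(unname(sf$avg_probs), unname(colMeans(ren)), tolerance = 2e-4)
  w <- df$weighted_score[!is.na(df$weighted_score)]
  expect_equal(sf$avg_weighted_class, mean(w), tolerance = 2e-4)
  for (k in 0:4) {
    mass <- ren[, k + 1] / sum(ren[, k + 1])
    h <- -sum(mass * log(mass)) / log(sum(usable))
    expect_equal(unname(sf$entropies[as.character(k)]), h, tolerance = 2e-3)
  }
  expect_equal(sf$n_tiles_used, sum(usable))
})

test_that("aggregation is invariant under tile permutation", {
  fm <- random_feature_map(6, 8, K = 4, seed = 19, ignore_scale = 0.4)
  set.seed(1)
  perm <- sample(nrow(fm$probs))
  fm2 <- feature_map(fm$probs[perm, ], fm$values, 6, 8)
  a <- aggregate_feature_map(fm); b <- aggregate_feature_map(fm2)
  expect_equal(a$avg_probs, b$avg_probs)
  expect_equal(a$avg_weighted_class, b$avg_weighted_class)
  expect_equal(a$entropies, b$entropies)
})

test_that("avg weighted class reconstructs from avg probs when no tile is missing", {
  fm <- random_feature_map(8, 8, K = 5, seed = 23, ignore_scale = 0.1)
  stopifnot(!any(is.na(map_weighted_scores <- apply(fm$probs, 1, tile_weighted_score,
                                                    values = fm$values))))
  sf <- aggregate_feature_map(fm)
  expect_equal(sf$avg_weighted_class, sum(fm$values * sf$avg_probs),
               tolerance = 1e-9)
  expect_equal(sum(sf$avg_probs), 1, tolerance = 1e-9)
  expect_true(all(sf$entropies >= 0 & sf$entropies <= 1))
})

test_that("maps without usable tiles are flagged missing with a warning", {
  probs <- matrix(rep(c(0, 0, 0, 0, 0, 1), 4), 4, byrow = TRUE)
  fm <- feature_map(probs, 0:4, 2, 2)
  expect_warning(sf <- aggregate_feature_map(fm), "flagged missing")
  expect_true(sf$missing)
  expect_equal(sf$n_tiles_used, 0L)
  # low-confidence flag below 5 usable tiles
  fm2 <- one_hot_map(1, 2, 2)
  expect_true(aggregate_feature_map(fm2)$low_confidence)
})

test_that("slide feature tables carry the 2K+1 layout", {
  sfs <- list(aggregate_feature_map(one_hot_map(2, 4, 4)))
  tab <- slide_features_table(sfs)
  expect_equal(ncol(tab), 3 + 5 + 1 + 5)
  v <- as_ann_input(sfs[[1]])
  expect_length(v, 11)
})
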
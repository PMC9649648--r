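test_that("classifier specs enforce the class schemes and scale coupling", {
  sb <- classifier_spec("ballooning")
  expect_equal(sb$labels, c("0", "1", "ignore"))
  expect_equal(sb$scale, "high")
  sf <- classifier_spec("fibrosis")
  expect_equal(sf$scale, "low")                 # fibrosis <=> low scale
  expect_equal(sf$labels, c(as.character(0:4), "ignore"))
  ss <- classifier_spec("steatosis")
  expect_equal(length(ss$values), 15)           # 5%-wide bins
  expect_true(all(diff(ss$values) > 0))
  expect_equal(tail(ss$labels, 1), "ignore")    # every head has ignore
  expect_error(classifier_spec("fibrosis", backbone = "inception_v3"),
               "no Inception-V3 implementation")
  expect_error(classifier_spec("steatosis", values = c(1, 99)), "invalid class")
})

test_that("the stratified split reproduces the 95/5 fraction exactly", {
  set.seed(71)
  labels <- sample(rep(c("0", "1", "2", "3", "ignore"), each = 200))
  sp <- split_tiles(labels, 0.95, seed = 1)
  expect_equal(length(sp$train), 950)
  expect_equal(length(sp$val), 50)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), seq_along(labels))
  # stratified: every class contributes to validation
  expect_setequal(unique(labels[sp$val]), unique(labels))
  # reproducible
  sp2 <- split_tiles(labels, 0.95, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_tiles(labels, 0.95, seed = 2)))
})

test_that("split edge cases warn and keep tiny classes whole in training", {
  expect_warning(sp <- split_tiles(rep("0", 50), 1.0), "empty validation")
  expect_length(sp$val, 0)
  labels <- c(rep("0", 40), "rare")
  expect_warning(sp2 <- split_tiles(labels, 0.9, seed = 1), "kept whole")
  expect_false(41 %in% sp2$val)
})

test_that("a small CNN learns visually separable steatosis bins", {
  fx <- small_cnn_fixture()
  h <- fx$model$history
  # the model keeps the best-validation-epoch weights
  expect_gte(h$val_acc[fx$model$best_epoch], 0.90)
  # confusion matrix trace / total equals that epoch's accuracy exactly
  expect_equal(sum(diag(fx$model$confusion)) / sum(fx$model$confusion),
               h$val_acc[fx$model$best_epoch])
})

test_that("probability outputs are normalized, order-preserving, size-checked", {
  fx <- small_cnn_fixture()
  X <- fx$tiles$x[, , , 1:8, drop = FALSE]
  p <- classify_tiles(fx$model, X)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # batches preserve order: per-tile calls agree with the batch
  for (i in c(1, 5, 8))
    expect_equal(unname(classify_tiles(fx$model, X[, , , i, drop = FALSE])[1, ]),
                 unname(p[i, ]))
  bad <- array(0.5, c(100, 100, 3))
  expect_error(classify_tiles(fx$model, bad), "not a 299 px")
})

test_that("blank glass routes to the ignore class after training", {
  fx <- small_cnn_fixture()
  blank <- array(0.985, c(299, 299, 3))
  p <- classify_tile(fx$model, blank)
  expect_equal(names(which.max(p)), "ignore")
})

test_that("zero-epoch training returns an initialized chance-level model", {
  fx <- small_cnn_fixture()
  m0 <- train_classifier(fx$spec,
                         train = list(x = fx$tiles$x, y = fx$tiles$y),
                         val = list(x = fx$tiles$x[, , , 1:40, drop = FALSE],
                                    y = fx$tiles$y[1:40]),
                         epochs = 0, seed = 1)
  expect_equal(nrow(m0$history), 0)
  p <- classify_tiles(m0, fx$tiles$x[, , , 1:40, drop = FALSE])
  acc <- mean(max.col(p) == match(fx$tiles$y[1:40], fx$spec$labels))
  expect_lt(acc, 0.6)                      # near chance for K = 4 balanced
})

test_that("training is deterministic: same seed, same weights checksum", {
  fx <- small_cnn_fixture()
  idx <- unlist(lapply(unique(fx$tiles$y), function(cl) which(fx$tiles$y == cl)[1:12]))
  sub <- list(x = fx$tiles$x[, , , idx, drop = FALSE], y = fx$tiles$y[idx])
  m1 <- train_classifier(fx$spec, sub, epochs = 2, seed = 5)
  m2 <- train_classifier(fx$spec, sub, epochs = 2, seed = 5)
  expect_identical(hepatoscore:::weights_checksum(m1),
                   hepatoscore:::weights_checksum(m2))
  m3 <- train_classifier(fx$spec, sub, epochs = 2, seed = 6)
  expect_false(identical(hepatoscore:::weights_checksum(m1),
                         hepatoscore:::weights_checksum(m3)))
})

test_that("training rejects class-free training sets and missing checkpoints", {
  fx <- small_cnn_fixture()
  keep <- fx$tiles$y != "ignore"
  expect_error(train_classifier(fx$spec,
                                list(x = fx$tiles$x[, , , keep, drop = FALSE],
                                     y = fx$tiles$y[keep]), epochs = 1),
               "absent from training set")
  spec_p <- classifier_spec("steatosis", values = c(1, 8, 13),
                            pretrained_mode = "imagenet")
  expect_error(train_classifier(spec_p, list(x = fx$tiles$x, y = fx$tiles$y),
                                epochs = 1), "requires init_from")
})

test_that("domain warm-starts train at least as well as cold starts", {
  fx <- small_cnn_fixture()
  # transfer task: different bin subset of the same feature family
  spec_cold <- classifier_spec("steatosis", values = c(2, 7, 12), input_px = 32,
                               channels = c(8L, 16L, 32L))
  tiles <- synthetic_training_tiles(spec_cold, 30, seed = 88)
  sp <- split_tiles(tiles$y, 0.8, seed = 1)
  tr <- list(x = tiles$x[, , , sp$train, drop = FALSE], y = tiles$y[sp$train])
  va <- list(x = tiles$x[, , , sp$val, drop = FALSE], y = tiles$y[sp$val])
  cold <- train_classifier(spec_cold, tr, va, epochs = 4, seed = 2, lr = 2e-3)
  spec_warm <- classifier_spec("steatosis", values = c(2, 7, 12), input_px = 32,
                               channels = c(8L, 16L, 32L),
                               pretrained_mode = "imagenet+domain")
  ckpt <- tempfile(fileext = ".rds")
  save_classifier(fx$model, ckpt)
  warm <- train_classifier(spec_warm, tr, va, epochs = 4, seed = 2, lr = 2e-3,
                           init_from = ckpt)
  a_cold <- cold$history$val_acc[4]
  a_warm <- warm$history$val_acc[4]
  expect_gte(a_warm, a_cold - 0.02)
})

test_that("checkpoints round-trip through disk", {
  fx <- small_cnn_fixture()
  path <- tempfile(fileext = ".rds")
  save_classifier(fx$model, path)
  m <- load_classifier(path)
  expect_identical(m$weights, fx$model$weights)
  expect_error(load_classifier({p <- tempfile(); saveRDS(1:3, p); p}),
               "not a tile_cnn")
})

test_that("class activation maps localize, normalize, and validate classes", {
  fx <- small_cnn_fixture()
  tile <- hepatoscore:::unclass_tile(generate_tile("steatosis", 13, seed = 301))
  cam <- class_activation_map(fx$model, tile, "13")
  expect_equal(dim(cam$map), c(299, 299))
  expect_gte(min(cam$map), 0); expect_lte(max(cam$map), 1)
  expect_true(cam$confidence >= 0 && cam$confidence <= 1)
  # constant input: no spatial signal, normalized to all zeros
  flat <- array(0.5, c(299, 299, 3))
  cam0 <- class_activation_map(fx$model, flat, "1")
  expect_true(all(cam0$map == 0))
  expect_error(class_activation_map(fx$model, tile, "7"), "unknown class")
})

test_that("fibrosis CAMs concentrate on the bridging streak", {
  fix <- pipeline_fixture()
  hits <- 0
  for (s in 1:3) {
    tl <- generate_tile("fibrosis", 3, mpp = 1.32, seed = 400 + s)
    mask_base <- attr(tl, "collagen_mask")
    mask <- hepatoscore:::block_mean(mask_base + 0, 3) > 0.3
    cam <- class_activation_map(fix$cnns$fibrosis, hepatoscore:::unclass_tile(tl), "3")
    on <- mean(cam$map[mask]); off <- mean(cam$map[!mask])
    if (isTRUE(on > off)) hits <- hits + 1
  }
  expect_gte(hits, 2)  # localization on the collagen structures
})
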
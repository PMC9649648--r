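# Shared end-to-end fixture: four trained tile CNNs, a 120-slide noiseless
# synthetic cohort mapped and aggregated per feature, out-of-fold scoring
# networks, and the per-slide collagen-area baseline.  Built once per test
# run (several minutes) and reused by the parameter-recovery and
# group-separation suites.

.hs_test_cache <- new.env(parent = emptyenv())

abind4 <- function(a, b) {
  out <- array(0, c(dim(a)[1:3], dim(a)[4] + dim(b)[4]))
  out[, , , seq_len(dim(a)[4])] <- a
  out[, , , dim(a)[4] + seq_len(dim(b)[4])] <- b
  out
}

fixture_sizes <- list(
  n_slides = 120L,
  tiles_per_class = c(ballooning = 200L, inflammation = 200L,
                      steatosis = 60L, fibrosis = 100L),
  cnn_epochs = c(ballooning = 20L, inflammation = 20L,
                 steatosis = 14L, fibrosis = 28L),
  cnn_channels = list(ballooning = c(12L, 24L, 48L, 48L),
                      inflammation = c(12L, 24L, 48L, 48L),
                      steatosis = c(8L, 16L, 32L, 32L),
                      fibrosis = c(12L, 24L, 48L, 48L)),
  cnn_lr = 2e-3,
  ann_epochs = 400L, folds = 4L,
  seed = 202L
)

pipeline_fixture <- function() {
  if (!is.null(.hs_test_cache$fix)) return(.hs_test_cache$fix)
  fs <- fixture_sizes
  cnns <- list()
  hard_neg <- c(ballooning = 0.5, inflammation = 0.4, steatosis = 0, fibrosis = 0)
  for (f in hs_features()) {
    spec <- classifier_spec(f, channels = fs$cnn_channels[[f]])
    tiles <- synthetic_training_tiles(spec, fs$tiles_per_class[[f]],
                                      seed = fs$seed + match(f, hs_features()),
                                      hard_negative_frac = hard_neg[[f]])
    if (f == "fibrosis") {
      # extra coverage of the subtle stage-0/1 boundary
      extra <- synthetic_training_tiles(spec, 120, seed = fs$seed + 17,
                                        classes = c("0", "1"))
      tiles <- list(x = abind4(tiles$x, extra$x), y = c(tiles$y, extra$y))
    }
    sp <- split_tiles(tiles$y, 0.95, seed = fs$seed)
    cnns[[f]] <- train_classifier(
      spec,
      train = list(x = tiles$x[, , , sp$train, drop = FALSE], y = tiles$y[sp$train]),
      val = list(x = tiles$x[, , , sp$val, drop = FALSE], y = tiles$y[sp$val]),
      epochs = fs$cnn_epochs[[f]], seed = fs$seed, lr = fs$cnn_lr)
  }
  # fibrosis-balanced noiseless cohort: uniform scores per feature
  manifest <- generate_cohort(fs$n_slides, score_mix = "uniform",
                              observer_noise_sd = 0, seed = fs$seed,
                              write_images = FALSE)
  specs <- attr(manifest, "specs")
  feats <- setNames(replicate(4, vector("list", fs$n_slides), simplify = FALSE),
                    hs_features())
  collagen_pct <- numeric(fs$n_slides)
  n_foci <- integer(fs$n_slides); n_balloon <- integer(fs$n_slides)
  for (i in seq_len(fs$n_slides)) {
    r <- render_slide(specs[[i]])
    slide <- r$slide
    n_foci[i] <- r$truth$n_foci; n_balloon[i] <- r$truth$n_balloon
    grids <- list(high = build_grid(slide, "high"), low = build_grid(slide, "low"))
    for (f in hs_features()) {
      fm <- map_slide(cnns[[f]], slide, grids[[cnns[[f]]$spec$scale]])
      feats[[f]][[i]] <- aggregate_feature_map(fm)
    }
    # stride-2 subsample: unbiased area estimate at a quarter of the pixels
    sub <- slide$pixels[seq(1, dim(slide$pixels)[1], 2),
                        seq(1, dim(slide$pixels)[2], 2), , drop = FALSE]
    collagen_pct[i] <- collagen_area_fraction(sub)
  }
  anns <- list(); records <- list()
  for (f in hs_features()) {
    X <- do.call(rbind, lapply(feats[[f]], as_ann_input))
    fit <- train_scoring_ann(X, manifest[[f]], f, folds = fs$folds,
                             seed = fs$seed, slide_ids = manifest$slide_id,
                             epochs = fs$ann_epochs)
    anns[[f]] <- fit
    records[[f]] <- fit$records
  }
  fix <- list(cnns = cnns, manifest = manifest, features = feats,
              anns = anns, records = do.call(rbind, records),
              collagen_pct = collagen_pct,
              n_foci = n_foci, n_balloon = n_balloon, sizes = fs)
  .hs_test_cache$fix <- fix
  fix
}

# Small trained classifier on a coarse steatosis task, cached; used by
# classifier unit tests that need a working (not necessarily strong) model.
small_cnn_fixture <- function() {
  if (!is.null(.hs_test_cache$small)) return(.hs_test_cache$small)
  spec <- classifier_spec("steatosis", values = c(1, 8, 13))
  tiles <- synthetic_training_tiles(spec, 90, seed = 77)
  sp <- split_tiles(tiles$y, 0.85, seed = 1)
  model <- train_classifier(
    spec,
    train = list(x = tiles$x[, , , sp$train, drop = FALSE], y = tiles$y[sp$train]),
    val = list(x = tiles$x[, , , sp$val, drop = FALSE], y = tiles$y[sp$val]),
    epochs = 20, seed = 1, lr = 2e-3)
  out <- list(spec = spec, tiles = tiles, split = sp, model = model)
  .hs_test_cache$small <- out
  out
}
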
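# End-to-end orchestration: manifest of slides in, continuous scores out.

#' Pipeline configuration
#'
#' Validated key-value configuration; unknown keys are rejected.
#'
#' @param ... Overrides of the defaults: `tile_px`, `mpp_high`, `mpp_low`,
#'   `min_tissue`, `input_px`, `cnn_epochs`, `cnn_lr`, `cnn_batch`,
#'   `ann_hidden`, `ann_epochs`, `ann_lr`, `folds`, `seed`,
#'   `export_feature_maps`, `features`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(tile_px = .hs_geometry$tile_px,
                   mpp_high = .hs_geometry$mpp_high,
                   mpp_low = .hs_geometry$mpp_low,
                   min_tissue = .hs_geometry$min_tissue,
                   input_px = 64L,
                   cnn_epochs = 10L, cnn_lr = 1e-3, cnn_batch = 32L,
                   ann_hidden = c(16L, 8L), ann_epochs = 400L, ann_lr = 0.01,
                   folds = 4L, seed = 1L,
                   export_feature_maps = FALSE,
                   features = hs_features())
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- modifyList(defaults, over)
  if (!all(cfg$features %in% hs_features()))
    stop("unknown feature in config", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with config keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Score a cohort of slides end-to-end
#'
#' For every manifest slide: load the TIFF, build both tile grids, run each
#' feature's CNN into a feature map, aggregate, and score with the feature's
#' scoring network; active-injury scores are summed into the NAS.
#'
#' @param manifest data.frame (or CSV path) with at least `slide_id` and
#'   `path`; a cohort manifest from [generate_cohort()] works directly.
#' @param models Named list with `cnn` and `ann`, each a named list keyed by
#'   feature (see [fit_synthetic_pipeline()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `scores.csv` (and feature
#'   map exports when configured).
#' @return data.frame of per-slide continuous scores (one column per
#'   feature, plus `nas` when all three injury features are scored).
#' @export
run_pipeline <- function(manifest, models, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("slide_id", "path") %in% names(manifest)))
  features <- config$features
  for (f in features) {
    if (is.null(models$cnn[[f]]))
      stop("no tile classifier available for feature '", f, "'", call. = FALSE)
    if (is.null(models$ann[[f]]))
      stop("no scoring model available for feature '", f, "'", call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$slide_id[i]
    if (is.na(manifest$path[i]) || !file.exists(manifest$path[i]))
      stop("slide '", id, "' not found on disk: ", manifest$path[i], call. = FALSE)
    slide <- load_slide(manifest$path[i], slide_id = id)
    scores <- score_slide(slide, models, config, out_dir)
    rows[[i]] <- cbind(data.frame(slide_id = id), as.data.frame(as.list(scores)))
  }
  out <- do.call(rbind, rows)
  if (all(c("steatosis", "inflammation", "ballooning") %in% names(out)))
    out$nas <- nas(out$steatosis, out$inflammation, out$ballooning)
  if (!is.null(out_dir))
    write.csv(out, file.path(out_dir, "scores.csv"), row.names = FALSE)
  out
}

#' Score a single slide
#'
#' @param slide A [slide_image()].
#' @param models,config As in [run_pipeline()].
#' @param out_dir Optional directory for feature-map exports.
#' @return Named numeric vector of continuous feature scores.
#' @export
score_slide <- function(slide, models, config = pipeline_config(), out_dir = NULL) {
  grids <- list(high = build_grid(slide, "high", config$tile_px),
                low = build_grid(slide, "low", config$tile_px))
  out <- setNames(rep(NA_real_, length(config$features)), config$features)
  for (f in config$features) {
    cnn <- models$cnn[[f]]
    fm <- map_slide(cnn, slide, grids[[cnn$spec$scale]], config$min_tissue)
    if (isTRUE(config$export_feature_maps) && !is.null(out_dir))
      export_feature_map(fm, file.path(out_dir, paste0(slide$slide_id, "_", f)))
    sf <- aggregate_feature_map(fm)
    if (!sf$missing) out[f] <- predict_score(models$ann[[f]], sf)
  }
  out
}

#' Train all pipeline models on synthetic data
#'
#' Desk-scale end-to-end training: per feature, a labeled synthetic tile set
#' is generated and a small-backbone CNN trained on a stratified 95/5
#' split; a synthetic cohort is then rendered, mapped and aggregated, and
#' per-feature scoring networks are fit by slide-level cross-validation
#' against the manifest's recorded scores.
#'
#' @param manifest Cohort manifest from [generate_cohort()] (its attached
#'   specs are used to render slides in memory when `path` is NA).
#' @param config A [pipeline_config()].
#' @param tiles_per_class Training tiles per class for each CNN (single
#'   value or named per feature).
#' @param features Features to train (default: all four).
#' @param verbose Print stage progress.
#' @return list with `cnn`, `ann` (named lists), `features` (per-slide
#'   `slide_features` by feature) and `records` (out-of-fold score records).
#' @export
fit_synthetic_pipeline <- function(manifest, config = pipeline_config(),
                                   tiles_per_class = 60L,
                                   features = hs_features(), verbose = FALSE) {
  specs_by_slide <- attr(manifest, "specs")
  if (length(tiles_per_class) == 1)
    tiles_per_class <- setNames(rep(tiles_per_class, length(features)), features)
  say <- function(...) if (verbose) message(sprintf(...))
  cnns <- list()
  for (f in features) {
    say("training %s CNN", f)
    cspec <- classifier_spec(f, input_px = config$input_px)
    tiles <- synthetic_training_tiles(cspec, tiles_per_class[[f]],
                                      seed = child_seed(config$seed, match(f, hs_features())))
    sp <- split_tiles(tiles$y, 0.95, seed = config$seed)
    cnns[[f]] <- train_classifier(
      cspec,
      train = list(x = tiles$x[, , , sp$train, drop = FALSE], y = tiles$y[sp$train]),
      val = list(x = tiles$x[, , , sp$val, drop = FALSE], y = tiles$y[sp$val]),
      epochs = config$cnn_epochs, seed = config$seed,
      lr = config$cnn_lr, batch = config$cnn_batch)
  }
  say("mapping %d slides", nrow(manifest))
  feats <- setNames(vector("list", length(features)), features)
  for (i in seq_len(nrow(manifest))) {
    slide <- if (!is.na(manifest$path[i]) && file.exists(manifest$path[i]))
      load_slide(manifest$path[i], slide_id = manifest$slide_id[i])
    else render_slide(specs_by_slide[[i]])$slide
    grids <- list(high = build_grid(slide, "high"), low = build_grid(slide, "low"))
    for (f in features) {
      fm <- map_slide(cnns[[f]], slide, grids[[cnns[[f]]$spec$scale]], config$min_tissue)
      feats[[f]][[i]] <- aggregate_feature_map(fm)
    }
  }
  anns <- list(); recs <- list()
  for (f in features) {
    say("fitting %s scoring network", f)
    X <- do.call(rbind, lapply(feats[[f]], as_ann_input))
    fit <- train_scoring_ann(X, manifest[[f]], f, folds = config$folds,
                             seed = config$seed, slide_ids = manifest$slide_id,
                             hidden = config$ann_hidden, epochs = config$ann_epochs,
                             lr = config$ann_lr)
    # final model refit on all slides for deployment; CV records kept
    keep <- !is.na(manifest[[f]])
    anns[[f]] <- fit_scoring_ann(X[keep, , drop = FALSE], manifest[[f]][keep],
                                 if (f == "nas") 8 else score_range(f),
                                 hidden = config$ann_hidden, epochs = config$ann_epochs,
                                 lr = config$ann_lr, seed = config$seed)
    recs[[f]] <- fit$records
  }
  list(cnn = cnns, ann = anns, features = feats,
       records = do.call(rbind, recs))
}
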
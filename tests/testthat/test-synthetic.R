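test_that("steatosis tiles realize their bin's area fraction exactly", {
  for (cl in c(0L, 4L, 9L, 14L)) {
    tl <- generate_tile("steatosis", cl, seed = 7 + cl)
    b <- steatosis_bins()[cl + 1, ]
    frac <- attr(tl, "vacuole_frac")
    expect_gte(frac, b$lo)
    expect_lt(frac, b$hi)
    # the realized fraction is measured on the generator's own mask
    expect_equal(frac, mean(attr(tl, "vacuole_mask")), tolerance = 1e-12)
  }
})

test_that("tiles are deterministic in the seed and valid 8-bit-range RGB", {
  a <- generate_tile("inflammation", 2, seed = 5)
  b <- generate_tile("inflammation", 2, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_equal(dim(a), c(299, 299, 3))
  expect_true(all(a >= 0 & a <= 1))
  c1 <- generate_tile("inflammation", 2, seed = 6)
  expect_false(identical(unclass(a), unclass(c1)))
})

test_that("class-defining content matches the shape ledger", {
  t0 <- generate_tile("ballooning", 0, seed = 1)
  expect_null(attr(t0, "balloon"))          # absence class: zero primitives
  t1 <- generate_tile("ballooning", 1, seed = 1)
  expect_gte(nrow(attr(t1, "balloon")), 1)
  i0 <- generate_tile("inflammation", 0, seed = 2)
  expect_null(attr(i0, "foci"))
  i2 <- generate_tile("inflammation", 2, seed = 2)
  expect_gte(nrow(attr(i2, "foci")), 3)
})

test_that("invalid class labels are rejected with explicit messages", {
  expect_error(generate_tile("ballooning", 2), "invalid class")
  expect_error(generate_tile("fibrosis", 5), "invalid class")
  expect_error(generate_tile("steatosis", 15), "invalid class")
  expect_error(generate_tile("inflammation", -1), "invalid class")
})

test_that("bridging fibrosis connects two portal rims in the collagen mask", {
  tl <- generate_tile("fibrosis", 3, mpp = 1.32, seed = 3)
  mask <- attr(tl, "collagen_mask")
  anchors <- attr(tl, "rim_anchors")
  expect_gte(nrow(anchors), 2)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab))
  # component id at the pixel nearest each of the two rim anchors
  comp_at <- function(x, y) {
    win <- lab[pmax(1, round(y) - 8):pmin(nrow(lab), round(y) + 8),
               pmax(1, round(x) - 8):pmin(ncol(lab), round(x) + 8)]
    ids <- win[win > 0]
    if (!length(ids)) NA else as.integer(names(sort(table(ids), decreasing = TRUE))[1])
  }
  c1 <- comp_at(anchors[1, 1], anchors[1, 2])
  c2 <- comp_at(anchors[2, 1], anchors[2, 2])
  expect_false(is.na(c1) || is.na(c2))
  expect_identical(c1, c2)
})

test_that("fibrosis stage collagen areas are monotone with a small stage-1 step", {
  area <- sapply(0:4, function(cl) {
    mean(sapply(1:6, function(s)
      mean(attr(generate_tile("fibrosis", cl, mpp = 1.32, seed = 100 * cl + s),
                "collagen_mask"))))
  })
  expect_true(all(diff(area) > 0))
  expect_lt(area[2] - area[1], 0.01)   # stage 1 adds < 1% area
  expect_gt(area[3], 0.015)            # stage >= 2 markedly elevated
})

test_that("slide ground truth derives from generative params via Kleiner rules", {
  spec <- synthetic_slide_spec("s", 897, 598, steatosis_area_frac = 0.20,
                               inflam_foci_per_field = 3,
                               ballooning_burden = "few", fibrosis_class = 2,
                               seed = 4)
  r <- render_slide(spec)
  expect_equal(r$truth$slide_scores[["steatosis"]], 1L)   # 20% -> 1
  expect_equal(r$truth$slide_scores[["inflammation"]], 2L) # 3 foci -> 2
  expect_equal(r$truth$slide_scores[["ballooning"]], 1L)
  expect_equal(r$truth$slide_scores[["fibrosis"]], 2L)
  # high-resolution per-tile grid of a 897 x 598 slide is 2 rows x 3 cols
  expect_equal(dim(r$truth$per_tile_labels$steatosis), c(2L, 3L))
})

test_that("null-pathology slides score zero everywhere", {
  spec <- synthetic_slide_spec("null", 897, 897, steatosis_area_frac = 0,
                               inflam_foci_per_field = 0,
                               ballooning_burden = "none", fibrosis_class = 0,
                               seed = 9)
  r <- render_slide(spec)
  expect_true(all(r$truth$slide_scores == 0))
  expect_equal(r$truth$n_foci, 0)
  expect_equal(r$truth$n_balloon, 0)
})

test_that("rendered slide steatosis tracks the spec within 0.02 (>= 9 tiles)", {
  spec <- synthetic_slide_spec("s", 897, 897, steatosis_area_frac = 0.30, seed = 21)
  r <- render_slide(spec, keep_masks = TRUE)
  expect_lt(abs(mean(r$masks$vacuole) - 0.30), 0.02)
  expect_true(all(abs(r$truth$tile_vacuole_frac - 0.30) < 0.02))
})

test_that("cohort manifests are reproducible and noiselessly round-trip", {
  m1 <- generate_cohort(20, write_images = FALSE, seed = 31)
  m2 <- generate_cohort(20, write_images = FALSE, seed = 31)
  attr(m1, "specs") <- attr(m2, "specs") <- NULL
  expect_identical(m1, m2)
  # noiseless: recorded scores equal ground-truth scores exactly, and both
  # equal the scores derived from the rendered slides' generative params
  m <- generate_cohort(10, write_images = FALSE, seed = 32)
  for (f in hs_features())
    expect_identical(m[[f]], m[[paste0("truth_", f)]])
  specs <- attr(m, "specs")
  derived <- t(vapply(specs, function(sp)
    render_slide(sp)$truth$slide_scores, numeric(4)))
  expect_equal(unname(derived[, "fibrosis"]), m$fibrosis)
  expect_equal(unname(derived[, "steatosis"]), m$steatosis)
})

test_that("uniform fibrosis mix hits binomial count bounds at n = 200", {
  m <- generate_cohort(200, write_images = FALSE, seed = 33)
  counts <- table(factor(m$fibrosis, levels = 0:4))
  expect_true(all(counts >= 20 & counts <= 60))
})

test_that("observer noise perturbs scores by at most one level, in range", {
  m <- generate_cohort(60, write_images = FALSE, seed = 34, observer_noise_sd = 0.8)
  for (f in hs_features()) {
    d <- abs(m[[f]] - m[[paste0("truth_", f)]])
    expect_true(all(d <= 1))
    expect_true(all(m[[f]] >= 0 & m[[f]] <= score_range(f)))
  }
  # sd 0.8 flips with probability ~0.53; across 240 recorded scores some move
  expect_gt(sum(abs(m$fibrosis - m$truth_fibrosis)), 0)
})

test_that("tile label tables and spec validation behave", {
  spec <- synthetic_slide_spec("s", 897, 598, fibrosis_class = 1, seed = 2)
  r <- render_slide(spec)
  tab <- tile_labels_table("s", r$truth)
  expect_true(all(c("slide_id", "feature", "row", "col", "label") %in% names(tab)))
  expect_equal(sum(tab$feature == "steatosis"), 6)   # 2 x 3 grid
  expect_error(synthetic_slide_spec("s", 100, 897), "one 299 px tile")
  expect_error(synthetic_slide_spec("s", 897, 897, fibrosis_class = 7), "0..4")
  expect_error(synthetic_slide_spec("s", 897, 897, steatosis_area_frac = 1.2))
})
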
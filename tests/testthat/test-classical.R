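test_that("Kleiner steatosis thresholds reproduce the printed mapping", {
  expect_equal(kleiner_steatosis_score(20), 1L)
  expect_equal(kleiner_steatosis_score(4.9), 0L)
  expect_equal(kleiner_steatosis_score(70), 3L)
  # boundary semantics: closed below, open above
  expect_equal(kleiner_steatosis_score(c(0, 5, 33, 33.01, 66, 66.01, 100)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(kleiner_steatosis_score(101), "\\[0, 100\\]")
  # total monotone step function over the domain
  g <- kleiner_steatosis_score(seq(0, 100, by = 0.25))
  expect_true(all(diff(g) >= 0))
})

test_that("Kleiner inflammation thresholds reproduce the printed mapping", {
  expect_equal(kleiner_inflammation_score(0), 0L)
  expect_equal(kleiner_inflammation_score(3), 2L)
  expect_equal(kleiner_inflammation_score(5), 3L)
  expect_equal(kleiner_inflammation_score(c(0.5, 1.9, 2, 4, 4.1)),
               c(1L, 1L, 2L, 2L, 3L))
  expect_error(kleiner_inflammation_score(-1), ">= 0")
  g <- kleiner_inflammation_score(seq(0, 10, by = 0.05))
  expect_true(all(diff(g) >= 0))
})

test_that("ballooning burden maps to 0/1/2", {
  expect_equal(kleiner_ballooning_score(c("none", "few", "many")), 0:2)
  expect_equal(kleiner_ballooning_score(c(0, 1, 3, 3.5)), c(0L, 1L, 1L, 2L))
  expect_error(kleiner_ballooning_score("lots"), "none/few/many")
})

test_that("steatosis area is recovered from rendered slides", {
  r <- render_slide(synthetic_slide_spec("a", 897, 897,
                                         steatosis_area_frac = 0.20, seed = 41),
                    keep_masks = TRUE)
  est <- steatosis_area_fraction(r$slide)
  expect_lt(abs(est - 20), 2)
  r0 <- render_slide(synthetic_slide_spec("b", 897, 897,
                                          steatosis_area_frac = 0, seed = 42))
  expect_lt(steatosis_area_fraction(r0$slide), 1)
  expect_true(is.na(steatosis_area_fraction(array(1, c(200, 200, 3)))))
})

test_that("stain models reject degenerate vector sets", {
  v <- cbind(c(1, 0, 0), c(2, 0, 0))
  expect_error(stain_model(v), "singular|dependent")
  expect_s3_class(stain_model_masson(), "stain_model")
  expect_s3_class(stain_model_synthetic(), "stain_model")
  expect_equal(colSums(stain_model_masson()$vectors^2), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unmixing then re-mixing reconstructs optical density", {
  sm <- stain_model_synthetic()
  set.seed(8)
  # synthetic two-stain image: random nonneg combinations of the stains
  n <- 40 * 40
  conc_true <- cbind(runif(n, 0, 0.8), runif(n, 0, 0.8), 0)
  od_true <- conc_true %*% t(sm$vectors)
  img <- array(pmin(1, pmax(0, (256 * 10^(-od_true) - 1) / 255)), c(40, 40, 3))
  conc <- stain_concentrations(img, sm)
  od_remix <- conc %*% t(sm$vectors)
  od_obs <- optical_density(img)
  expect_lt(max(abs(od_remix - od_obs)), 1e-6)
})

test_that("painted collagen area is recovered within two points", {
  sm <- stain_model_synthetic()
  set.seed(12)
  cv <- hepatoscore:::canvas_new(400, 400)
  hepatoscore:::add_tissue(cv)
  # paint the configured collagen color over 30% of the tissue
  target <- 0.30
  while (mean(cv$col) < target) {
    hepatoscore:::paint_collagen(cv, hepatoscore:::ellipse_idx(
      400, 400, runif(1, 1, 400), runif(1, 1, 400), runif(1, 15, 40), runif(1, 15, 40)))
  }
  est <- collagen_area_fraction(cv$img, sm)
  expect_lt(abs(est - 100 * mean(cv$col)), 2)
  # Beer-Lambert null: pure white image has no optical density anywhere
  expect_true(is.na(collagen_area_fraction(array(1, c(100, 100, 3)), sm)))
  expect_equal(max(abs(optical_density(array(1, c(10, 10, 3))))), 0,
               tolerance = 1e-3)
})

test_that("group comparison is calibrated under the null and powered under shift", {
  set.seed(21)
  # null: groups are permutations of the same distribution
  ps <- replicate(100, {
    v <- rnorm(40)
    g <- sample(rep(0:1, each = 20))
    group_comparison(v, g)$p_adj[2]
  })
  expect_gt(median(ps), 0.05)
  # power: +3 SD shift at n = 20 per group
  ps2 <- replicate(20, {
    v <- c(rnorm(20), rnorm(20, 3))
    g <- rep(0:1, each = 20)
    group_comparison(v, g)$p_adj[2]
  })
  expect_true(all(ps2 < 0.01))
  # control vs itself: p = 1 by convention; tiny groups flagged
  gc <- group_comparison(c(rnorm(20), 0.5), c(rep(0, 20), 1))
  expect_equal(gc$p[gc$group == "0"], 1)
  expect_true(gc$flagged[gc$group == "1"])
})
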
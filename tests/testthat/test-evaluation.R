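test_that("discretization rounds half up and clips to the scale", {
  expect_identical(discretize_score(2.5, 4), 3L)
  expect_identical(discretize_score(0.49, 4), 0L)
  expect_identical(discretize_score(4.0, 4), 4L)
  expect_identical(discretize_score(c(-0.2, 4.7), 4), c(0L, 4L))
})

test_that("MAE uses continuous predictions and excludes missing truth", {
  expect_equal(score_mae(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(score_mae(c(1, 2), c(0, 4)), 1.5)
  x <- runif(20, 0, 4); y <- sample(0:4, 20, TRUE)
  expect_equal(score_mae(x + 0.37, y), score_mae(x, y - 0.37))  # shift by c
  expect_equal(score_mae(c(1, 99), c(1, NA)), 0)
  expect_error(score_mae(numeric(0), numeric(0)), "no scored pairs")
})

test_that("quadratic weighted kappa matches hand-computed cases", {
  expect_equal(quadratic_weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3), 0:3), 1)
  # two-level anti-diagonal: complete systematic disagreement
  expect_equal(quadratic_weighted_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1), 0:1), -1)
  # both raters constant and equal: zero expected disagreement, defined as 1
  expect_equal(quadratic_weighted_kappa(c(2, 2), c(2, 2), 0:4), 1)
  expect_error(quadratic_weighted_kappa(c(0, 9), c(0, 1), 0:4), "outside")
})

test_that("kappa equals the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:300) {
    K <- sample(2:9, 1)
    n <- sample(5:500, 1)
    levels <- 0:(K - 1)
    truth <- sample(levels, n, TRUE)
    pred <- sample(levels, n, TRUE)
    expect_lt(abs(quadratic_weighted_kappa(pred, truth, levels) -
                  oracle_qwk(pred, truth, levels)), 1e-12)
  }
})

test_that("normalizing the quadratic weights by S^2 leaves kappa unchanged", {
  # the shared factor cancels between numerator and denominator; check by
  # comparing against the oracle that uses unnormalized (i - j)^2 weights
  set.seed(7)
  truth <- sample(0:4, 300, TRUE)
  pred <- pmin(4, pmax(0, truth + sample(-1:1, 300, TRUE)))
  expect_equal(quadratic_weighted_kappa(pred, truth, 0:4),
               oracle_qwk(pred, truth, 0:4), tolerance = 1e-12)
})

test_that("weighted precision/recall/F1 match the oracle and closed forms", {
  expect_equal(weighted_prf(c(0, 1, 2), c(0, 1, 2), 0:2),
               c(precision = 1, recall = 1, f1 = 1))
  # constant prediction, uniform truth over 5 levels: recall = support share
  truth <- rep(0:4, each = 20)
  pred <- rep(2, 100)
  expect_equal(weighted_prf(pred, truth, 0:4)[["recall"]], 0.2)
  set.seed(11)
  for (rep in 1:50) {
    K <- sample(2:6, 1); n <- sample(10:200, 1)
    truth <- sample(0:(K - 1), n, TRUE); pred <- sample(0:(K - 1), n, TRUE)
    expect_equal(weighted_prf(pred, truth, 0:(K - 1)),
                 oracle_prf(pred, truth, 0:(K - 1)), tolerance = 1e-12)
  }
})

test_that("support-weighted recall equals overall accuracy", {
  set.seed(3)
  for (rep in 1:100) {
    K <- sample(2:9, 1); n <- sample(5:300, 1)
    truth <- sample(0:(K - 1), n, TRUE); pred <- sample(0:(K - 1), n, TRUE)
    expect_equal(weighted_prf(pred, truth, 0:(K - 1))[["recall"]],
                 mean(pred == truth), tolerance = 1e-12)
  }
})

test_that("discretization moves MAE by at most one half", {
  set.seed(5)
  pred <- runif(200, 0, 4); truth <- sample(0:4, 200, TRUE)
  m1 <- score_mae(pred, truth)
  m2 <- score_mae(discretize_score(pred, 4), truth)
  expect_gte(m2, 0)
  expect_lte(abs(m1 - m2), 0.5)
})

test_that("evaluate_scores builds per-feature rows plus a NAS row", {
  set.seed(9)
  n <- 40
  mk <- function(f, smax) data.frame(
    slide_id = sprintf("s%02d", 1:n), feature = f,
    truth = sample(0:smax, n, TRUE), ai_score = runif(n, 0, smax))
  rec <- rbind(mk("ballooning", 2), mk("inflammation", 3),
               mk("steatosis", 3), mk("fibrosis", 4))
  rec$truth[rec$feature == "fibrosis"][1:3] <- NA   # missing scores
  rep <- evaluate_scores(rec, dataset = "unit")
  expect_s3_class(rep, "eval_report")
  expect_setequal(rep$score, c(hs_features(), "nas"))
  expect_equal(rep$n[rep$score == "fibrosis"], n - 3)
  expect_equal(rep$n[rep$score == "nas"], n)
  nasr <- rep[rep$score == "nas", ]
  expect_true(nasr$mae >= 0 && abs(nasr$kappa_qw) <= 1)
  conf <- attr(rep, "confusion")
  expect_equal(sum(conf$fibrosis), n - 3)          # confusion total = n
  expect_equal(dim(conf$nas), c(9L, 9L))           # NAS levels 0..8
  # deterministic re-emission
  rep2 <- evaluate_scores(rec, dataset = "unit")
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
})
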
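test_that("confusion counts enumerate pixel agreement", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  tr <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  cc <- confusion(m, tr)
  expect_equal(as.list(cc), list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))

  truth <- matrix(c(rep(TRUE, 3), rep(FALSE, 6)), 3, 3)
  perfect <- confusion(truth, truth)
  expect_equal(perfect$TP, 3L)
  expect_equal(perfect$TN, 6L)
  expect_equal(perfect$FP + perfect$FN, 0L)

  allmiss <- confusion(matrix(FALSE, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(allmiss$FN, 9L)
  expect_equal(allmiss$TP + allmiss$TN + allmiss$FP, 0L)

  expect_error(confusion(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "dimensions")
})

test_that("supervised scores match direct arithmetic", {
  sc <- supervised_scores(list(TP = 3, FP = 1, FN = 2, TN = 4))
  expect_equal(sc$jaccard, 0.5)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 0.6)
  expect_equal(sc$fscore, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(sc$accuracy, 0.7)
  expect_equal(sc$flags, "")

  perfect <- supervised_scores(list(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(perfect$jaccard, 1)
  expect_equal(perfect$fscore, 1)
  expect_equal(perfect$accuracy, 1)

  none <- supervised_scores(list(TP = 0, FP = 2, FN = 3, TN = 5))
  expect_equal(none$jaccard, 0)
  expect_equal(none$fscore, 0)
  expect_true(nzchar(none$flags))

  expect_error(supervised_scores(list(TP = 0, FP = 0, FN = 0, TN = 0)),
    "empty comparison"
  )
  expect_error(supervised_scores(list(TP = -1, FP = 0, FN = 0, TN = 2)),
    "non-negative"
  )
})

test_that("jaccard never exceeds fscore and scores stay in [0, 1]", {
  set.seed(601)
  for (r in 1:1000) {
    cc <- as.list(setNames(rpois(4, sample(c(0.5, 5, 50), 1)),
      c("TP", "TN", "FP", "FN")
    ))
    if (cc$TP + cc$TN + cc$FP + cc$FN == 0) next
    sc <- supervised_scores(cc)
    vals <- c(sc$jaccard, sc$precision, sc$recall, sc$fscore, sc$accuracy)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(sc$jaccard, sc$fscore + 1e-12)
    if (cc$TP + cc$FP + cc$FN > 0 && sc$fscore > 0) {
      expect_equal(sc$jaccard, sc$fscore / (2 - sc$fscore), tolerance = 1e-12)
    }
  }
})

test_that("jaccard and accuracy are symmetric under FP/FN swap", {
  set.seed(602)
  for (r in 1:50) {
    cc <- as.list(setNames(rpois(4, 10) + c(1, 0, 0, 0),
      c("TP", "TN", "FP", "FN")
    ))
    sw <- cc
    sw$FP <- cc$FN
    sw$FN <- cc$FP
    a <- supervised_scores(cc)
    b <- supervised_scores(sw)
    expect_equal(a$jaccard, b$jaccard)
    expect_equal(a$accuracy, b$accuracy)
  }
})

test_that("image uniformity matches hand arithmetic and conventions", {
  img <- matrix(c(rep(50L, 8), rep(200L, 8)), 4, 4)
  expect_equal(as.numeric(image_uniformity(img, 100)), 1)

  img4 <- matrix(c(0L, 0L, 100L, 200L), 1, 4)
  iu <- image_uniformity(img4, 50)
  expect_equal(as.numeric(iu), 1 - 2500 / 20000)

  const <- image_uniformity(matrix(9L, 2, 2), 100)
  expect_equal(as.numeric(const), 1)
  expect_equal(attr(const, "flags"), "constant_image")

  # nominal Z uses the full dynamic range
  iun <- image_uniformity(img4, 50, z_range = "nominal")
  expect_equal(as.numeric(iun), 1 - 2500 / (255^2 / 2))

  # invariant under adding a constant to all intensities (observed Z)
  expect_equal(
    as.numeric(image_uniformity(img4 + 20L, 70)),
    as.numeric(iu)
  )
})

test_that("region contrast matches hand arithmetic and flags degeneracy", {
  img <- matrix(c(rep(50L, 8), rep(150L, 8)), 4, 4)
  expect_equal(as.numeric(region_contrast(img, 100)), 100 / 200)

  maxc <- matrix(c(rep(0L, 8), rep(200L, 8)), 4, 4)
  expect_equal(as.numeric(region_contrast(maxc, 100)), 1)

  same <- matrix(rep(c(80L, 80L), 8), 4, 4)
  rc <- region_contrast(same, 100) # all pixels in one region
  expect_equal(as.numeric(rc), 0)
  expect_equal(attr(rc, "flags"), "empty_region")

  zz <- matrix(0L, 2, 2)
  rc0 <- region_contrast(zz, 100)
  expect_equal(as.numeric(rc0), 0)
})

test_that("all five metrics stay in [0, 1] on fuzzed inputs", {
  set.seed(603)
  for (r in 1:25) {
    img <- rand_image(12, 12, L = 256)
    truth <- matrix(sample(c(TRUE, FALSE), 144, replace = TRUE), 12, 12)
    t <- sample(0:255, 1)
    ev <- evaluate_segmentation(img, t, truth = truth)
    vals <- c(ev$IU, ev$RC, ev$jaccard, ev$fscore, ev$accuracy)
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("evaluate_segmentation assembles family means and flags", {
  g <- generate_image(mixture_template("well_separated", seed = 5))
  fit <- threshold_image(g$image, "otsu_lognormal")
  ev <- evaluate_segmentation(g$image, fit, g$truth)
  expect_equal(ev$supervised_mean, mean(c(ev$jaccard, ev$fscore, ev$accuracy)))
  expect_equal(ev$unsupervised_mean, mean(c(ev$IU, ev$RC)))
  expect_equal(ev$t_star, fit$t_star)

  unsup <- evaluate_segmentation(g$image, fit, metrics = "unsupervised")
  expect_true(is.na(unsup$jaccard))
  expect_false(is.na(unsup$IU))
  expect_error(
    evaluate_segmentation(g$image, fit, metrics = "supervised"),
    "ground truth"
  )
})
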
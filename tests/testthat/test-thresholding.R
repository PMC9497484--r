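two_spike_hist <- function(lo = 50, hi = 200, n_each = 10) {
  counts <- numeric(256)
  counts[lo + 1] <- n_each
  counts[hi + 1] <- n_each
  gray_histogram(counts)
}

test_that("all three objectives agree on a two-spike histogram", {
  h <- two_spike_hist()
  for (m in c("otsu_gaussian", "otsu_modified", "otsu_lognormal")) {
    curve <- otsu_curve(h, m)
    expect_equal(attr(curve, "t_star"), 50L, info = m)
    expect_true(all(is.finite(curve$value)))
    expect_true(all(curve$value >= 0))
  }
  # objective is flat over the tie region between the spikes
  g <- otsu_gaussian_curve(h)
  expect_equal(length(unique(g$value[g$t %in% 50:199])), 1L)
})

test_that("single-bin histograms give an all-zero curve with t* = 0", {
  counts <- numeric(256)
  counts[123 + 1] <- 42
  h <- gray_histogram(counts)
  for (m in c("otsu_gaussian", "otsu_modified", "otsu_lognormal")) {
    curve <- otsu_curve(h, m)
    expect_true(all(curve$value == 0), info = m)
    expect_equal(attr(curve, "t_star"), 0L, info = m)
  }
})

test_that("rational and explicit Gaussian forms agree everywhere", {
  set.seed(501)
  for (r in 1:30) {
    h <- rand_hist()
    a <- otsu_gaussian_curve(h, form = "rational")$value
    b <- otsu_gaussian_curve(h, form = "explicit")$value
    expect_true(all(abs(a - b) <= 1e-9 * pmax(abs(b), 1)))
  }
})

test_that("gaussian argmax matches the direct-sum scan oracle", {
  set.seed(502)
  for (r in 1:30) {
    h <- rand_hist()
    curve <- otsu_gaussian_curve(h)
    expect_equal(attr(curve, "t_star"), oracle_argmax(oracle_between_curve(h$p)))
  }
  # uniform histogram: symmetric curve, smallest maximizer returned
  hu <- gray_histogram(rep(4, 256))
  expect_equal(
    attr(otsu_gaussian_curve(hu), "t_star"),
    oracle_argmax(oracle_between_curve(hu$p))
  )
})

test_that("log_means reproduces hand-computed values", {
  counts0 <- numeric(256)
  counts0[0 + 1] <- 5
  h0 <- gray_histogram(counts0)
  expect_equal(log_means(h0, 10)$mu_T_log, 0) # log(0 + 1)

  counts6 <- numeric(256)
  counts6[6 + 1] <- 5
  h6 <- gray_histogram(counts6)
  expect_equal(log_means(h6, 10)$mu_T_log, log(7), tolerance = 1e-12)

  lm <- log_means(two_spike_hist(), 100)
  expect_equal(lm$mu_o_log, log(51))
  expect_equal(lm$mu_b_log, log(201))
  expect_equal(lm$mu_T_log, 0.5 * (log(51) + log(201)))
})

test_that("log-mean weighted decomposition holds when classes non-empty", {
  set.seed(503)
  for (r in 1:20) {
    h <- rand_hist()
    lm <- log_means(h)
    cs <- class_stats(h)
    nd <- !lm$degenerate
    lhs <- cs$Po[nd] * lm$mu_o_log[nd] + cs$Pb[nd] * lm$mu_b_log[nd]
    expect_true(all(abs(lhs - lm$mu_T_log[nd]) < 1e-9))
  }
})

test_that("modified rational form equals the explicit log-space variance", {
  set.seed(504)
  for (r in 1:100) {
    h <- rand_hist()
    a <- otsu_modified_curve(h)$value
    b <- otsu_lognormal_curve(h)$value
    expect_true(all(abs(a - b) <= 1e-9 * pmax(abs(b), 1)))
  }
})

test_that("lognormal argmax equals gaussian otsu on log-mapped bin values", {
  set.seed(505)
  for (r in 1:100) {
    h <- rand_hist()
    lam <- log(0:255 + 1)
    expect_equal(
      attr(otsu_lognormal_curve(h), "t_star"),
      oracle_argmax(oracle_between_curve(h$p, vals = lam))
    )
  }
})

test_that("lognormal t* is invariant under padding with empty high bins", {
  set.seed(506)
  for (r in 1:10) {
    h <- rand_hist(L = 256)
    hp <- gray_histogram(c(h$count, numeric(64)), L = 320L)
    expect_equal(
      attr(otsu_lognormal_curve(h), "t_star"),
      attr(otsu_lognormal_curve(hp), "t_star")
    )
  }
})

test_that("skip-zero log map excludes bin 0 from the log-means", {
  counts <- numeric(256)
  counts[0 + 1] <- 50
  counts[10 + 1] <- 25
  counts[100 + 1] <- 25
  h <- gray_histogram(counts)
  lm <- log_means(h, 50, log_map = "skip-zero")
  expect_equal(lm$mu_o_log, log(10)) # bin 0 carries no weight
  expect_equal(lm$mu_b_log, log(100))
  expect_equal(lm$mu_T_log, 0.5 * (log(10) + log(100)))
  # all mass at 0 leaves nothing for the lognormal model
  h0 <- gray_histogram(c(10, numeric(255)))
  curve <- otsu_lognormal_curve(h0, log_map = "skip-zero")
  expect_true(all(curve$value == 0))
})

test_that("curves are deterministic across repeated evaluation", {
  set.seed(507)
  h <- rand_hist()
  for (m in c("otsu_gaussian", "otsu_modified", "otsu_lognormal")) {
    c1 <- otsu_curve(h, m)
    c2 <- otsu_curve(h, m)
    expect_identical(c1$value, c2$value)
    expect_identical(attr(c1, "t_star"), attr(c2, "t_star"))
  }
})

test_that("threshold_image separates a two-valued image exactly", {
  img <- matrix(c(rep(50L, 30), rep(200L, 34)), 8, 8)
  for (m in c("otsu_gaussian", "otsu_modified", "otsu_lognormal")) {
    fit <- threshold_image(img, m)
    expect_identical(fit$mask, img > fit$t_star)
    expect_identical(fit$mask, matrix(img == 200L, 8, 8), info = m)
    expect_false(fit$degenerate)
  }
  inv <- threshold_image(img, "otsu_gaussian", invert = TRUE)
  expect_identical(inv$mask, matrix(img == 50L, 8, 8))
})

test_that("constant images are flagged degenerate with an all-false mask", {
  img <- matrix(77L, 6, 6)
  expect_warning(fit <- threshold_image(img, "otsu_lognormal"), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(fit$t_star, 0L)
  expect_false(any(fit$mask))
})

test_that("threshold results expose tidy, glance and curve output", {
  g <- generate_image(mixture_template("well_separated", seed = 3))
  fit <- threshold_image(g$image, "otsu_lognormal")
  td <- tidy(fit)
  expect_equal(nrow(td), 256L)
  expect_named(td, c("method", "t", "value"))
  gl <- glance(fit)
  expect_equal(gl$t_star, fit$t_star)
  expect_equal(gl$n_object + gl$n_background, length(g$image))
  f <- tempfile(fileext = ".csv")
  write_curve_csv(fit$curve, f)
  expect_equal(nrow(read.csv(f)), 256L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
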
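test_that("Cover-Hart bounds are exact at the anchor points", {
  expect_equal(cover_hart_bounds(0.32), c(lower = 0.20, upper = 0.32))
  expect_equal(cover_hart_bounds(0), c(lower = 0, upper = 0))
  expect_equal(cover_hart_bounds(0.5), c(lower = 0.5, upper = 0.5))
  # c-class generalization collapses to the binary form at c = 2
  expect_equal(cover_hart_bounds(0.3, 2)[["lower"]],
               (1 - sqrt(1 - 2 * 0.3)) / 2)
  expect_error(cover_hart_bounds(0.6), "outside")
  expect_error(cover_hart_bounds(-0.1), "outside")
  # monotone: larger R_nn never decreases either bound
  r <- seq(0, 0.5, by = 0.01)
  b <- vapply(r, cover_hart_bounds, c(lower = 0, upper = 0))
  expect_true(all(diff(b["lower", ]) >= 0))
  expect_true(all(diff(b["upper", ]) >= 0))
  expect_true(all(b["lower", ] <= b["upper", ] + 1e-12))
})

test_that("LOO nearest-neighbor error matches the plain-R oracle, ties included", {
  set.seed(21)
  for (k in c(1L, 3L)) {
    X <- matrix(rnorm(60 * 3), 60, 3)
    y <- rbinom(60, 1, 0.5)
    expect_equal(nn_error(X, y, k = k), r_loo_knn_error(X, y, k = k))
  }
  # exact duplicated points force distance ties
  Xd <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 1)
  yd <- c(0, 0, 0, 0, 1, 1)
  expect_equal(nn_error(Xd, yd, k = 1), r_loo_knn_error(Xd, yd, k = 1))
  expect_equal(nn_error(Xd, yd, k = 1), 0)
  # a tied vote falls to class 0
  Xt <- matrix(c(0, 1, 2), ncol = 1)
  yt <- c(1, 0, 1)
  expect_equal(nn_error(Xt, yt, k = 2), r_loo_knn_error(Xt, yt, k = 2))
})

test_that("LOO 1-NN error agrees with class::knn.cv on tie-free data", {
  skip_if_not_installed("class")
  set.seed(22)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- rbinom(300, 1, 0.5)
  Xs <- scale(X)
  ref <- mean(as.integer(as.character(class::knn.cv(Xs, factor(y), k = 1))) != y)
  expect_equal(nn_error(X, y, k = 1), ref)
})

test_that("nearest-neighbor error behaves at the separable and random extremes", {
  set.seed(23)
  # two tight, well-separated clusters with pure labels
  X <- rbind(matrix(rnorm(100 * 2, 0, 0.1), 100, 2),
             matrix(rnorm(100 * 2, 10, 0.1), 100, 2))
  y <- rep(0:1, each = 100)
  expect_equal(nn_error(X, y), 0)
  # coin-flip labels on noise features: error near 1/2
  Xn <- matrix(rnorm(2000 * 3), 2000, 3)
  yn <- rbinom(2000, 1, 0.5)
  e <- nn_error(Xn, yn)
  expect_gt(e, 0.45); expect_lt(e, 0.55)
  # scale invariance after standardization
  expect_equal(nn_error(Xn * 1000, yn), e)
  expect_error(nn_error(Xn[1, , drop = FALSE], 0), "at least")
})

test_that("bound estimates bracket the analytic Gaussian Bayes error", {
  g <- gaussian_dataset(6000, d = 2, delta = 2, seed = 31)
  est <- bound_estimate(g$X, g$y, seed = 31)
  expect_lte(est$lower - 0.02, g$bayes_error)
  expect_gte(est$upper + 0.02, g$bayes_error)
  expect_lte(est$lower, est$upper)
  expect_equal(est$n, 6000)
  # identical inputs give identical estimates
  est2 <- bound_estimate(g$X, g$y, seed = 31)
  expect_identical(est, est2)
})

test_that("bound curves are pointwise-consistent bands over nested sizes", {
  g <- gaussian_dataset(3000, d = 2, delta = 4, seed = 33)
  crv <- bound_curve(g$X, g$y, c(500, 1000, 3000), seed = 1)
  expect_equal(crv$size, c(500, 1000, 3000))
  expect_true(all(crv$lower <= crv$upper))
  # separable-ish data: both curve levels small at every size
  gs <- gaussian_dataset(2000, d = 2, delta = 10, seed = 34)
  cs <- bound_curve(gs$X, gs$y, c(500, 2000), seed = 1)
  expect_true(all(cs$upper <= 0.02))
  # a single size reproduces bound_estimate exactly
  c1 <- bound_curve(g$X, g$y, 3000, seed = 1)
  e1 <- bound_estimate(g$X, g$y)
  expect_equal(c1$r_nn, e1$r_nn)
  expect_equal(c1$lower, e1$lower)
})

test_that("no classifier in the suite beats the estimated Bayes floor", {
  pf <- planted_features(1500, n_informative = 4, n_noise = 8,
                         label_noise = 0.15, seed = 35)
  est <- bound_estimate(pf$X, pf$y)
  rf <- cv_train_eval(pf$X, pf$y, rf_spec(num_trees = 80), seed = 3)
  ert <- cv_train_eval(pf$X, pf$y, ert_spec(num_trees = 80), seed = 3)
  expect_gte(rf$mean_error, est$lower - 0.02)
  expect_gte(ert$mean_error, est$lower - 0.02)
  expect_gte(rf$mean_error, pf$bayes_error - 0.02)
})
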
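make_xy <- function(n = 400, p = 10, seed = 1, noise = 0) {
  pf <- planted_features(n, n_informative = 3, n_noise = p - 3,
                         label_noise = noise, seed = seed)
  list(X = pf$X, y = pf$y)
}

test_that("correlation ranking finds perfect correlates and demotes constants", {
  set.seed(1)
  y <- rbinom(200, 1, 0.5)
  X <- cbind(exact = y, flipped = 1 - y, noise = rnorm(200), const = 1)
  r <- correlation_rank(X, y)
  expect_equal(r$feature[1:2], c("exact", "flipped"))
  expect_equal(abs(r$correlation[1]), 1)
  expect_equal(r$correlation[r$feature == "const"], 0)
  expect_equal(r$feature[4], "const")
  # direct point-biserial cross-check
  expect_equal(r$correlation[r$feature == "noise"], cor(X[, "noise"], y))
  expect_error(correlation_rank(X, rep(1, 200)), "single class")
})

test_that("cross-validation is deterministic, stratified and separable-exact", {
  d <- make_xy(320, seed = 2)
  spec <- rf_spec(num_trees = 60)
  cv1 <- cv_train_eval(d$X, d$y, spec, seed = 11)
  cv2 <- cv_train_eval(d$X, d$y, spec, seed = 11)
  expect_identical(cv1, cv2)
  expect_equal(cv1$mean_error, mean(cv1$fold_errors))
  # folds partition the rows
  test_ids <- unlist(lapply(cv1$folds, `[[`, "test"))
  expect_setequal(test_ids, rownames(d$X))
  expect_equal(length(test_ids), nrow(d$X))

  # a single perfectly informative binary feature: near-zero error
  set.seed(3)
  y <- rbinom(240, 1, 0.5)
  X <- cbind(signal = y, matrix(rnorm(240 * 4), 240, 4))
  cv <- cv_train_eval(X, y, spec, seed = 1)
  expect_lt(cv$mean_error, 0.02)
})

test_that("coin-flip labels give chance-level error", {
  set.seed(4)
  n <- 1200
  X <- matrix(rnorm(n * 6), n, 6)
  y <- rbinom(n, 1, 0.5)
  cv <- cv_train_eval(X, y, rf_spec(num_trees = 60), seed = 5)
  expect_gt(cv$mean_error, 0.45)
  expect_lt(cv$mean_error, 0.55)
})

test_that("cv results are invariant to row permutation given row ids", {
  d <- make_xy(240, seed = 6)
  spec <- rf_spec(num_trees = 40)
  cv_a <- cv_train_eval(d$X, d$y, spec, seed = 7)
  set.seed(8)
  perm <- sample(nrow(d$X))
  cv_b <- cv_train_eval(d$X[perm, ], d$y[perm], spec, seed = 7)
  expect_equal(cv_a$mean_error, cv_b$mean_error)
  expect_equal(cv_a$fold_errors, cv_b$fold_errors)
})

test_that("per-fold feature selection never sees the test fold", {
  d <- make_xy(160, p = 6, seed = 9)
  spec <- rf_spec(num_trees = 30)
  cv0 <- cv_train_eval(d$X, d$y, spec, seed = 13, select_k = 2)
  # plant a leak: a feature equal to the labels on fold 1's TEST rows only,
  # pure noise on its training rows
  test1 <- cv0$folds[[1]]$test
  leak <- rnorm(nrow(d$X))
  leak[match(test1, rownames(d$X))] <- d$y[match(test1, rownames(d$X))] * 10
  X2 <- cbind(d$X, leak = leak)
  cv1 <- cv_train_eval(X2, d$y, spec, seed = 13, select_k = 2)
  expect_false("leak" %in% cv1$selected_features[[1]])
  # and the fold-1 selection is identical to the leak-free run
  expect_identical(cv1$selected_features[[1]], cv0$selected_features[[1]])
})

test_that("feature-count curves collapse to plain CV at the full width", {
  d <- make_xy(200, p = 8, seed = 10)
  spec <- rf_spec(num_trees = 40)
  crv <- error_vs_num_features(d$X, d$y, k_grid = 8, spec, seed = 3)
  cv <- cv_train_eval(d$X, d$y, spec, seed = 3, select_k = 8)
  expect_equal(nrow(crv), 1)
  expect_equal(crv$mean_error, cv$mean_error)
  expect_error(error_vs_num_features(d$X, d$y, integer(0), spec), "empty")
})

test_that("size curves are nested, skip tiny sizes, and match plain CV at N", {
  d <- make_xy(400, seed = 12, noise = 0.15)
  spec <- rf_spec(num_trees = 40)
  crv <- error_vs_dataset_size(d$X, d$y, c(100, 200, 400), spec, seed = 4)
  expect_equal(crv$x, c(100, 200, 400))
  cvN <- cv_train_eval(d$X, d$y, spec, seed = 4)
  expect_equal(crv$mean_error[3], cvN$mean_error)
  expect_warning(error_vs_dataset_size(d$X, d$y, c(6, 400), spec, seed = 4),
                 "skipped")
  # doubling n never worsens the error beyond sampling noise
  for (i in 2:3) {
    pooled <- sqrt(mean(crv$std_error[(i - 1):i]^2))
    expect_lte(crv$mean_error[i], crv$mean_error[i - 1] + 2 * pooled + 1e-9)
  }
})

test_that("Gini importances are seed-stable and spotlight planted signal", {
  pf <- planted_features(300, n_informative = 1, n_noise = 9,
                         label_noise = 0, seed = 15)
  gs <- gini_importance_stability(pf$X, pf$y, rf_spec(num_trees = 60),
                                  n_runs = 3)
  top <- gs$importance$feature[which.max(gs$importance$mean)]
  expect_equal(top, "inf_01")
  # identical seeds give identical importances
  g1 <- gini_importance_stability(pf$X, pf$y, rf_spec(num_trees = 40),
                                  n_runs = 2, seeds = c(5, 5))
  expect_equal(g1$importance$sd, rep(0, 10))
  # graded planted effects: the importance ranking is highly reproducible,
  # and clearly more so than the pure-noise baseline (on a fixed design
  # matrix even uninformative columns keep dataset-conditional importance
  # levels, so the null agreement is above zero but well below the signal)
  set.seed(20)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, c(paste0("inf", 1:4), paste0("ns", 1:6))))
  X[, 1:4] <- X[, 1:4] + y %o% c(2, 1.2, 0.7, 0.4)
  gg <- gini_importance_stability(X, y, rf_spec(num_trees = 60), n_runs = 4)
  expect_gt(gg$mean_rank_correlation, 0.9)
  set.seed(16)
  Xn <- matrix(rnorm(n * 10), n, 10,
               dimnames = list(NULL, paste0("n", 1:10)))
  yn <- rbinom(n, 1, 0.5)
  gn <- gini_importance_stability(Xn, yn, rf_spec(num_trees = 60), n_runs = 4)
  expect_lt(gn$mean_rank_correlation, gg$mean_rank_correlation - 0.15)
})

test_that("LASSO-logistic matches the forest on easy problems", {
  pf <- planted_features(600, n_informative = 3, n_noise = 7,
                         label_noise = 0, seed = 17)
  acc <- lasso_logistic_check(pf$X, pf$y, seed = 2)
  expect_gt(as.numeric(acc), 0.95)
  rf <- cv_train_eval(pf$X, pf$y, rf_spec(num_trees = 60), seed = 2)
  expect_lt(abs((1 - rf$mean_error) - as.numeric(acc)), 0.1)
  # subsampling is honored
  acc_sub <- lasso_logistic_check(pf$X, pf$y, subsample_n = 300, seed = 2)
  expect_equal(attr(acc_sub, "cv")$n, 300)
})

test_that("regression RMSE hits zero on deterministic targets", {
  set.seed(18)
  X <- matrix(rnorm(500 * 4), 500, 4)
  y <- 2 * X[, 1] - X[, 2]
  rmse <- rf_regression_rmse(X, y, seed = 1, num_trees = 80)
  expect_lt(rmse, 0.6 * sd(y))
  expect_warning(r0 <- rf_regression_rmse(X, rep(5, 500), seed = 1), "constant")
  expect_equal(r0, 0)
})

test_that("PCA projections separate separated classes with stable signs", {
  set.seed(19)
  n <- 200
  y <- rep(0:1, each = n / 2)
  # class shift spread over three correlated columns so the leading
  # standardized PC aligns with the between-class direction
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 1:3] <- X[, 1:3] + y * 4
  p1 <- pca_projection(X, y)
  p2 <- pca_projection(X, y)
  expect_identical(p1$scores, p2$scores)
  mu <- tapply(p1$scores$PC1, p1$scores$class, mean)
  pooled_sd <- sqrt(mean(tapply(p1$scores$PC1, p1$scores$class, var)))
  expect_gt(abs(diff(mu)) / pooled_sd, 4)
  # identical class distributions: centroids coincide
  Xn <- matrix(rnorm(n * 5), n, 5)
  pn <- pca_projection(Xn, y)
  mun <- tapply(pn$scores$PC1, pn$scores$class, mean)
  expect_lt(abs(diff(mun)), 0.5)
})
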
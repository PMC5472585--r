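# Bayes (irreducible) classification error bounds.
#
# The Bayes error R* is the lowest misclassification probability any
# classifier can reach given the feature representation. It is bracketed
# from the asymptotic nearest-neighbor error rate R_NN by the Cover-Hart
# relation: for a binary problem,
#
#     (1 - sqrt(1 - 2 R_NN)) / 2  <=  R*  <=  R_NN,
#
# with the c-class generalization
# lower = ((c-1)/c) (1 - sqrt(1 - c R_NN / (c-1))). R_NN is estimated here
# by leave-one-out k-NN on per-feature standardized columns under the
# Euclidean metric, with deterministic tie handling so estimates are exactly
# reproducible. If a cross-validated classifier's error approaches the lower
# bound, its residual error is intrinsic to the representation, not a model
# deficiency.

standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1  # constant columns carry no distance
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Leave-one-out k-nearest-neighbor error rate
#'
#' Each point is classified by majority vote of its k nearest other points
#' (squared Euclidean distance on standardized features). Distance ties are
#' broken toward the smaller row index and vote ties toward the smaller
#' class, so the estimate is deterministic.
#'
#' @param X numeric feature matrix.
#' @param y binary (0/1) labels, or a factor/character vector (classes are
#'   taken in sorted order).
#' @param k neighbor count (default 1).
#' @param standardize standardize columns to zero mean / unit variance first.
#' @return the misclassification rate, a scalar in `[0, 1]`.
#' @export
nn_error <- function(X, y, k = 1L, standardize = TRUE) {
  X <- as.matrix(X)
  lev <- sort(unique(y))
  yi <- as.integer(match(y, lev)) - 1L
  if (nrow(X) != length(yi)) stop("X rows and y length differ")
  if (nrow(X) < k + 1L) stop("need at least k + 1 rows")
  if (standardize) X <- standardize_columns(X)
  storage.mode(X) <- "double"
  pred <- loo_knn_pred_cpp(X, yi, as.integer(k), length(lev))
  mean(pred != yi)
}

#' Cover-Hart bracket on the Bayes error from an NN error rate
#'
#' @param R_nn nearest-neighbor error rate, in `[0, (c-1)/c]`.
#' @param n_classes number of classes c (default binary).
#' @return named vector `c(lower, upper)` with
#'   `lower = ((c-1)/c) (1 - sqrt(max(0, 1 - c R_nn/(c-1))))` and
#'   `upper = R_nn`.
#' @export
cover_hart_bounds <- function(R_nn, n_classes = 2L) {
  c_ <- as.integer(n_classes)
  stopifnot(c_ >= 2L, length(R_nn) == 1L, is.finite(R_nn))
  if (R_nn < 0 || R_nn > (c_ - 1) / c_) {
    stop("R_nn = ", R_nn, " outside [0, ", (c_ - 1) / c_, "]")
  }
  lower <- ((c_ - 1) / c_) * (1 - sqrt(max(0, 1 - c_ * R_nn / (c_ - 1))))
  c(lower = lower, upper = R_nn)
}

#' Bracket the Bayes error of a labeled feature matrix
#'
#' Composes [nn_error()] and [cover_hart_bounds()] and records the metric and
#' standardization metadata for reproducibility.
#'
#' @inheritParams nn_error
#' @param seed recorded in the estimate for provenance; the computation
#'   itself is deterministic.
#' @return a `bayes_bound_estimate`: `r_nn`, `lower`, `upper`, `n`, `k`,
#'   `metric`, `standardized`, `seed`.
#' @export
bound_estimate <- function(X, y, k = 1L, standardize = TRUE, seed = NA_integer_) {
  r <- nn_error(X, y, k = k, standardize = standardize)
  b <- cover_hart_bounds(r, n_classes = length(unique(y)))
  structure(list(r_nn = r, lower = unname(b["lower"]), upper = unname(b["upper"]),
                 n = nrow(as.matrix(X)), k = as.integer(k),
                 metric = "euclidean", standardized = standardize,
                 seed = seed),
            class = "bayes_bound_estimate")
}

#' @export
print.bayes_bound_estimate <- function(x, ...) {
  cat("<bayes_bound_estimate> R_NN = ", fmt_num(x$r_nn),
      "  =>  Bayes error in [", fmt_num(x$lower), ", ", fmt_num(x$upper),
      "]\n  (n = ", x$n, ", k = ", x$k, ", ", x$metric,
      if (x$standardized) ", standardized", ")\n", sep = "")
  invisible(x)
}

#' Bayes-error bound band as a function of dataset size
#'
#' Bounds computed on nested stratified subsamples (the sample at each size
#' is a subset of the next), so the band is comparable across sizes.
#'
#' @inheritParams bound_estimate
#' @param size_grid increasing sample sizes, each at most `nrow(X)`.
#' @param seed integer seed for the nested subsampling.
#' @return a `bound_curve` data.frame: `size`, `r_nn`, `lower`, `upper`.
#' @export
bound_curve <- function(X, y, size_grid, k = 1L, seed = 1L, standardize = TRUE) {
  X <- as.matrix(X)
  stopifnot(length(size_grid) >= 1L, max(size_grid) <= nrow(X))
  ord <- nested_stratified_order(y, derive_seed(seed, "bound_subsample"))
  rows <- lapply(sort(size_grid), function(nn) {
    idx <- sort(ord[seq_len(nn)])
    est <- bound_estimate(X[idx, , drop = FALSE], y[idx], k = k,
                          standardize = standardize, seed = seed)
    data.frame(size = nn, r_nn = est$r_nn, lower = est$lower, upper = est$upper)
  })
  structure(do.call(rbind, rows), class = c("bound_curve", "data.frame"),
            k = k, seed = seed)
}
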
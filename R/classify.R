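# Classifier training and evaluation under stratified four-fold
# cross-validation: random forests, extremely randomized trees and
# L1-penalized logistic regression, with per-fold correlation-based feature
# selection, error curves over descriptor counts and dataset sizes, Gini
# importance stability, and a regression RMSE check.

#' Model specifications
#'
#' `rf_spec()` is a random forest, `ert_spec()` an extremely randomized tree
#' ensemble (random split thresholds), `lasso_spec()` an L1-penalized
#' logistic regression whose penalty is chosen by internal cross-validation
#' on the training folds only.
#'
#' @param num_trees ensemble size.
#' @param mtry features per split; default `floor(sqrt(p))`.
#' @param min_node_size minimal node size; ranger defaults when NULL.
#' @return a `model_spec`.
#' @export
rf_spec <- function(num_trees = 200L, mtry = NULL, min_node_size = NULL) {
  structure(list(type = "rf", num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = min_node_size), class = "model_spec")
}

#' @rdname rf_spec
#' @export
ert_spec <- function(num_trees = 200L, mtry = NULL, min_node_size = NULL) {
  structure(list(type = "ert", num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = min_node_size), class = "model_spec")
}

#' @param nfolds_internal internal CV folds for the penalty path.
#' @rdname rf_spec
#' @export
lasso_spec <- function(nfolds_internal = 5L) {
  structure(list(type = "lasso", nfolds_internal = as.integer(nfolds_internal)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$type,
      if (x$type != "lasso") paste0(" (", x$num_trees, " trees)"), "\n", sep = "")
  invisible(x)
}

# guarantee usable, unique column names on a feature matrix
ensure_colnames <- function(X) {
  nm <- colnames(X)
  if (is.null(nm)) nm <- rep("", ncol(X))
  blank <- is.na(nm) | nm == ""
  nm[blank] <- sprintf("V%04d", which(blank))
  colnames(X) <- make.unique(nm)
  X
}

# fit on (Xtr, ytr); returns function(Xte) -> integer predictions in {0,1}
fit_classifier <- function(spec, Xtr, ytr, seed) {
  if (spec$type %in% c("rf", "ert")) {
    # probability forest: tree-averaged class frequencies give deterministic
    # predictions (majority-vote forests break exact vote ties with the
    # global RNG); ties at 0.5 fall to class 0 by the package convention
    fit <- ranger::ranger(
      x = Xtr, y = factor(ytr, levels = c(0, 1)),
      num.trees = spec$num_trees,
      mtry = spec$mtry %||% max(1L, floor(sqrt(ncol(Xtr)))),
      min.node.size = spec$min_node_size %||% 1L,
      splitrule = if (spec$type == "ert") "extratrees" else "gini",
      num.random.splits = 1L,
      probability = TRUE,
      num.threads = 1L, seed = seed, verbose = FALSE
    )
    function(Xte) {
      pr <- predict(fit, data = Xte, num.threads = 1L)$predictions
      as.integer(pr[, "1"] > 0.5)
    }
  } else if (spec$type == "lasso") {
    foldid <- with_seed(seed, sample(rep_len(seq_len(spec$nfolds_internal),
                                             nrow(Xtr))))
    fit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                             foldid = foldid)
    function(Xte) {
      as.integer(predict(fit, newx = Xte, s = "lambda.min", type = "class"))
    }
  } else stop("unknown model type: ", spec$type)
}

#' Rank features by correlation with a binary label
#'
#' Features ordered by decreasing absolute point-biserial correlation
#' (Pearson correlation with the 0/1 label). Constant columns get
#' correlation 0 and rank last; remaining ties break by column name.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary labels.
#' @return data.frame `feature`, `correlation`, ordered by decreasing
#'   `abs(correlation)`.
#' @export
correlation_rank <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (nrow(X) < 2L) stop("need at least 2 rows")
  X <- ensure_colnames(X)
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  r[!is.finite(r)] <- 0  # constant columns
  nm <- colnames(X)
  ord <- order(-abs(r), nm)
  data.frame(feature = nm[ord], correlation = r[ord], stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validated misclassification error
#'
#' The rows are split into stratified folds keyed on row ids; the model is
#' trained on k-1 parts and scored on the held-out part, and fold errors are
#' averaged. When `select_k` is given, features are ranked by
#' [correlation_rank()] INSIDE each training fold (no test-fold leakage) and
#' the top k are used; `selection = "global"` instead ranks once on all rows,
#' mimicking protocols that select before splitting.
#'
#' @param X feature matrix (rownames used as row ids when present).
#' @param y binary 0/1 labels.
#' @param model_spec a [rf_spec()], [ert_spec()] or [lasso_spec()].
#' @param folds number of folds (default 4).
#' @param seed integer; folds and model fits derive substreams from it.
#' @param select_k number of top-correlated features to keep; NULL = all.
#' @param selection `"per_fold"` (default, leakage-free) or `"global"`.
#' @return a `cv_result`: `fold_errors`, `mean_error`, `std_error`, per-fold
#'   id sets, the seed and the model type.
#' @export
cv_train_eval <- function(X, y, model_spec = rf_spec(), folds = 4L, seed = 1L,
                          select_k = NULL, selection = c("per_fold", "global")) {
  selection <- match.arg(selection)
  X <- ensure_colnames(as.matrix(X))
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (min(table(y)) < folds) stop("need at least ", folds, " rows per class")
  ids <- rownames(X) %||% sprintf("row%07d", seq_len(nrow(X)))
  fold_of <- stratified_folds(y, ids, folds, derive_seed(seed, "folds"))
  if (!is.null(select_k) && select_k > ncol(X)) {
    stop("select_k exceeds the number of columns")
  }
  global_rank <- if (!is.null(select_k) && selection == "global") {
    correlation_rank(X, y)$feature
  }
  fold_errors <- numeric(folds)
  fold_ids <- vector("list", folds)
  sel_features <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    tr <- tr[order(ids[tr])]; te <- te[order(ids[te])]  # row-order invariance
    cols <- colnames(X)
    if (!is.null(select_k)) {
      cols <- if (selection == "per_fold") {
        correlation_rank(X[tr, , drop = FALSE], y[tr])$feature[seq_len(select_k)]
      } else utils::head(global_rank, select_k)
    }
    pred_fn <- fit_classifier(model_spec, X[tr, cols, drop = FALSE], y[tr],
                              seed = derive_seed(seed, paste0("fit", f)))
    pred <- pred_fn(X[te, cols, drop = FALSE])
    fold_errors[f] <- mean(pred != y[te])
    fold_ids[[f]] <- list(train = ids[tr], test = ids[te])
    sel_features[[f]] <- cols
  }
  structure(list(fold_errors = fold_errors,
                 mean_error = mean(fold_errors),
                 std_error = stats::sd(fold_errors),
                 folds = fold_ids,
                 selected_features = sel_features,
                 model = model_spec$type, n = nrow(X), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$model, ", ", length(x$fold_errors),
      "-fold CV on n = ", x$n, "\n  mean error ", fmt_num(x$mean_error),
      " (sd ", fmt_num(x$std_error), "); folds: ",
      paste(fmt_num(x$fold_errors, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

new_curve <- function(x, y, yerr, xlab) {
  structure(data.frame(x = x, mean_error = y, std_error = yerr),
            class = c("audit_curve", "data.frame"), xlab = xlab)
}

#' Cross-validated error as a function of the number of features
#'
#' For each k in `k_grid`, runs [cv_train_eval()] on the top-k features
#' (selected per training fold). The error typically falls with k until the
#' informative features are exhausted, then plateaus.
#'
#' @inheritParams cv_train_eval
#' @param k_grid feature counts, each at most `ncol(X)`.
#' @return an `audit_curve` data.frame: `x` (k), `mean_error`, `std_error`.
#' @export
error_vs_num_features <- function(X, y, k_grid, model_spec = rf_spec(),
                                  folds = 4L, seed = 1L,
                                  selection = "per_fold") {
  if (length(k_grid) == 0L) stop("empty k_grid")
  stopifnot(max(k_grid) <= ncol(X))
  res <- lapply(sort(k_grid), function(k) {
    cv_train_eval(X, y, model_spec, folds, seed, select_k = k,
                  selection = selection)
  })
  new_curve(sort(k_grid),
            vapply(res, `[[`, 0, "mean_error"),
            vapply(res, `[[`, 0, "std_error"),
            xlab = "number of features")
}

#' Cross-validated error as a function of dataset size
#'
#' Stratified nested subsamples (each smaller sample is a subset of the
#' larger), then [cv_train_eval()] at each size.
#'
#' @inheritParams cv_train_eval
#' @param size_grid sample sizes, each at most `nrow(X)`; sizes with fewer
#'   than 4 rows per class are skipped with a warning.
#' @return an `audit_curve` data.frame.
#' @export
error_vs_dataset_size <- function(X, y, size_grid, model_spec = rf_spec(),
                                  folds = 4L, seed = 1L, select_k = NULL) {
  X <- as.matrix(X)
  stopifnot(max(size_grid) <= nrow(X))
  ids <- rownames(X) %||% sprintf("row%07d", seq_len(nrow(X)))
  rownames(X) <- ids
  ord <- nested_stratified_order(y, derive_seed(seed, "size_subsample"))
  xs <- c(); ys <- c(); es <- c()
  for (nn in sort(size_grid)) {
    idx <- sort(ord[seq_len(nn)])
    if (min(table(y[idx])) < max(4L, folds)) {
      warning("size ", nn, " has fewer than ", max(4L, folds),
              " rows in a class; skipped")
      next
    }
    cv <- cv_train_eval(X[idx, , drop = FALSE], y[idx], model_spec, folds,
                        seed, select_k = select_k)
    xs <- c(xs, nn); ys <- c(ys, cv$mean_error); es <- c(es, cv$std_error)
  }
  new_curve(xs, ys, es, xlab = "dataset size")
}

#' Stability of Gini (mean decrease in impurity) feature importances
#'
#' Fits the forest `n_runs` times with different seeds and reports the
#' per-feature importance mean and sd plus the Spearman rank correlation of
#' importances between every pair of runs.
#'
#' @inheritParams cv_train_eval
#' @param n_runs number of repeated fits (>= 2).
#' @param seeds optional explicit seeds, length `n_runs`.
#' @return list with `importance` (data.frame feature/mean/sd),
#'   `rank_correlations` (n_runs x n_runs Spearman matrix), and
#'   `mean_rank_correlation` (off-diagonal mean).
#' @export
gini_importance_stability <- function(X, y, model_spec = rf_spec(),
                                      n_runs = 5L, seeds = NULL) {
  stopifnot(n_runs >= 2L)
  seeds <- seeds %||% seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  X <- ensure_colnames(as.matrix(X))
  imp <- sapply(seeds, function(s) {
    fit <- ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)),
      num.trees = model_spec$num_trees %||% 200L,
      mtry = model_spec$mtry %||% max(1L, floor(sqrt(ncol(X)))),
      splitrule = if (identical(model_spec$type, "ert")) "extratrees" else "gini",
      num.random.splits = 1L,
      importance = "impurity", num.threads = 1L, seed = s, verbose = FALSE
    )
    fit$variable.importance
  })
  rho <- suppressWarnings(stats::cor(imp, method = "spearman"))
  list(
    importance = data.frame(feature = rownames(imp),
                            mean = rowMeans(imp),
                            sd = apply(imp, 1, stats::sd),
                            stringsAsFactors = FALSE),
    rank_correlations = rho,
    mean_rank_correlation = mean(rho[upper.tri(rho)])
  )
}

#' LASSO-logistic accuracy check on a subsample
#'
#' L1-penalized logistic regression (penalty chosen by internal CV on the
#' training folds), evaluated with the same stratified 4-fold scheme as the
#' forests, on a stratified subsample.
#'
#' @inheritParams cv_train_eval
#' @param subsample_n rows to use (stratified, seeded); NULL = all.
#' @return the cross-validated accuracy (scalar), with the full `cv_result`
#'   as attribute `"cv"`.
#' @export
lasso_logistic_check <- function(X, y, subsample_n = NULL, seed = 1L,
                                 folds = 4L) {
  X <- as.matrix(X)
  ids <- rownames(X) %||% sprintf("row%07d", seq_len(nrow(X)))
  rownames(X) <- ids
  if (!is.null(subsample_n)) {
    stopifnot(subsample_n <= nrow(X))
    ord <- nested_stratified_order(y, derive_seed(seed, "lasso_subsample"))
    idx <- sort(ord[seq_len(subsample_n)])
    X <- X[idx, , drop = FALSE]; y <- y[idx]
  }
  cv <- cv_train_eval(X, y, lasso_spec(), folds = folds, seed = seed)
  structure(1 - cv$mean_error, cv = cv)
}

#' Random-forest regression RMSE under k-fold cross-validation
#'
#' Pooled root-mean-square error of held-out predictions, on the target's
#' natural scale.
#'
#' @inheritParams cv_train_eval
#' @param y_continuous numeric target (e.g. yield in 0-100).
#' @param num_trees ensemble size.
#' @return the pooled RMSE (scalar).
#' @export
rf_regression_rmse <- function(X, y_continuous, seed = 1L, folds = 4L,
                               num_trees = 200L) {
  X <- ensure_colnames(as.matrix(X))
  y <- as.numeric(y_continuous)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) {
    warning("constant target; RMSE is 0")
    return(0)
  }
  ids <- rownames(X) %||% sprintf("row%07d", seq_len(nrow(X)))
  # quartile-binned stratification keeps fold target distributions comparable
  breaks <- unique(stats::quantile(y, c(0, .25, .5, .75, 1)))
  bins <- if (length(breaks) > 2L) {
    cut(y, breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(y))
  fold_of <- stratified_folds(bins, ids, folds, derive_seed(seed, "reg_folds"))
  sq <- numeric(0)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                          num.trees = num_trees,
                          mtry = max(1L, floor(ncol(X) / 3)),
                          num.threads = 1L,
                          seed = derive_seed(seed, paste0("regfit", f)),
                          verbose = FALSE)
    pred <- predict(fit, data = X[te, , drop = FALSE], num.threads = 1L)$predictions
    sq <- c(sq, (pred - y[te])^2)
  }
  sqrt(mean(sq))
}

#' Standardized PCA projection with class labels
#'
#' Zero-variance columns are dropped before scaling. Component signs follow
#' the convention that each component's largest-magnitude loading is
#' positive, so projections are reproducible.
#'
#' @inheritParams cv_train_eval
#' @param n_components number of components to return.
#' @return list with `scores` (data.frame of PCs plus `class`), `loadings`,
#'   and `explained_variance` (proportions).
#' @export
pca_projection <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  keep <- apply(X, 2, stats::sd) > 0
  if (sum(keep) < n_components) stop("fewer varying columns than components")
  p <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(p$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  list(scores = data.frame(scores, class = y),
       loadings = loadings,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)])
}

#' @export
plot.audit_curve <- function(x, add_band = NULL, ...) {
  graphics::plot(x$x, x$mean_error, type = "b", pch = 16,
                 xlab = attr(x, "xlab"), ylab = "CV misclassification error",
                 ylim = range(c(x$mean_error - x$std_error,
                                x$mean_error + x$std_error,
                                if (!is.null(add_band)) c(add_band$lower, add_band$upper))),
                 ...)
  graphics::arrows(x$x, x$mean_error - x$std_error,
                   x$x, x$mean_error + x$std_error,
                   angle = 90, code = 3, length = 0.03)
  if (!is.null(add_band)) {
    graphics::polygon(c(add_band$size, rev(add_band$size)),
                      c(add_band$lower, rev(add_band$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  }
  invisible(x)
}
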
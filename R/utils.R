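#' @useDynLib rxnaudit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp predict pnorm runif rnorm rbinom sd var cor quantile
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in a pipeline run descends from one top-level seed; each
#' stage draws from its own named substream so that changing, say, the CLD
#' mining seed does not perturb classifier fold assignment.
#'
#' @param seed integer top-level seed.
#' @param stream character name of the substream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- digest::digest(list(as.integer(seed), stream), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stratified fold assignment keyed on row ids: the id -> fold map depends only
# on the sorted ids, the labels and the seed, never on row order.
stratified_folds <- function(y, ids, folds = 4L, seed = 1L) {
  stopifnot(length(y) == length(ids), !anyDuplicated(ids))
  ord <- order(ids)
  assign_sorted <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y[ord]))) {
      members <- which(y[ord] == cl)
      if (length(members) < folds) {
        stop("class ", cl, " has fewer rows (", length(members),
             ") than folds (", folds, ")")
      }
      f <- rep_len(seq_len(folds), length(members))
      assign_sorted[members] <- sample(f)
    }
  })
  out <- integer(length(y))
  out[ord] <- assign_sorted
  out
}

# Nested stratified subsample indices: the sample of size n1 < n2 is a subset
# of the sample of size n2, so size curves are comparable.
nested_stratified_order <- function(y, seed) {
  n <- length(y)
  ord <- integer(0)
  with_seed(seed, {
    per_class <- lapply(split(seq_len(n), y), sample)
    # interleave classes proportionally so every prefix is ~stratified
    counts <- lengths(per_class)
    pos <- numeric(length(per_class))
    taken <- integer(length(per_class))
    ord <- integer(n)
    for (i in seq_len(n)) {
      frac <- (taken + 1) / counts          # next pick's fill fraction per class
      j <- which.min(ifelse(taken < counts, frac, Inf))
      taken[j] <- taken[j] + 1L
      ord[i] <- per_class[[j]][taken[j]]
    }
  })
  ord
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
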
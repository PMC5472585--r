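# Synthetic data generators with analytically known ground truth.
#
# Three tiers, all pure functions of their spec (seed included):
#   * gaussian_dataset(): feature-space two-class Gaussians whose Bayes error
#     is available in closed form -- the oracle for the bound estimators.
#   * planted_features(): a feature matrix with designated informative
#     columns, a deterministic linear label rule and optional label-flip
#     noise, so the true Bayes error equals the flip rate.
#   * planted_reactions(): SMILES-level reaction records built from a small
#     fragment grammar, with the label rule planted on heteroatom/halogen
#     decoration counts (which surface as descriptor columns), plus
#     literature-style mess: duplicates with conflicting outcomes and missing
#     fields. messy_records() additionally exercises every rejection path of
#     the cleaning stage with a manifest of exact expected counts.

#' Two-class Gaussian dataset with known Bayes error
#'
#' Class means sit at -delta/2 and +delta/2 on the first axis (all other
#' coordinates standard normal noise), unit covariance. For equal priors the
#' Bayes error is `pnorm(-delta/2)` in closed form.
#'
#' @param n number of points.
#' @param d dimension (>= 1).
#' @param delta class-mean separation along the first axis.
#' @param priors class prior probabilities, summing to 1.
#' @param seed integer seed.
#' @return list `X` (n x d), `y` (0/1), `bayes_error` (closed form for equal
#'   priors, else NA), `spec`.
#' @export
gaussian_dataset <- function(n, d = 2L, delta = 2, priors = c(0.5, 0.5),
                             seed = 1L) {
  stopifnot(n >= 2L, d >= 1L, delta >= 0)
  if (length(priors) != 2L || abs(sum(priors) - 1) > 1e-8 || any(priors < 0)) {
    stop("priors must be two non-negative numbers summing to 1")
  }
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, priors[2])
    X <- matrix(stats::rnorm(n * d), n, d)
  })
  X[, 1] <- X[, 1] + ifelse(y == 1L, delta / 2, -delta / 2)
  colnames(X) <- paste0("x", seq_len(d))
  rownames(X) <- sprintf("g%07d", seq_len(n))
  be <- if (abs(priors[1] - 0.5) < 1e-12) stats::pnorm(-delta / 2) else NA_real_
  list(X = X, y = y, bayes_error = be,
       spec = list(n = n, d = d, delta = delta, priors = priors, seed = seed))
}

#' Planted-feature classification dataset
#'
#' Standard-normal features; the first `n_informative` columns drive a
#' deterministic linear rule (`score = beta * rowSums > 0`), the rest are
#' pure noise. Labels are then flipped with probability `label_noise`, so
#' the Bayes error of the generated labels given X is exactly `label_noise`.
#'
#' @param n rows.
#' @param n_informative,n_noise column counts.
#' @param beta effect size (weight of each informative column).
#' @param label_noise flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list `X`, `y`, `informative` (column names), `truth`
#'   (`clean_labels`, `score`, `flipped`), `bayes_error`.
#' @export
planted_features <- function(n, n_informative = 10L, n_noise = 90L, beta = 1,
                             label_noise = 0, seed = 1L) {
  stopifnot(n >= 2L, n_informative >= 1L, n_noise >= 0L,
            label_noise >= 0, label_noise < 0.5)
  p <- n_informative + n_noise
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    flipped <- stats::rbinom(n, 1L, label_noise) == 1L
  })
  colnames(X) <- c(sprintf("inf_%02d", seq_len(n_informative)),
                   if (n_noise > 0) sprintf("noise_%02d", seq_len(n_noise)))
  rownames(X) <- sprintf("p%07d", seq_len(n))
  score <- beta * rowSums(X[, seq_len(n_informative), drop = FALSE])
  clean <- as.integer(score > 0)
  y <- ifelse(flipped, 1L - clean, clean)
  list(X = X, y = y, informative = colnames(X)[seq_len(n_informative)],
       truth = list(clean_labels = clean, score = score, flipped = flipped),
       bayes_error = label_noise)
}

## ---- reaction grammar ----

# Backbone = an alkyl chain of 3-6 carbons carrying exactly TWO single-atom
# substituents at distinct positions. Five decorations (F, Cl, Br, amino,
# thiol) are "informative": the planted label rule thresholds their total
# count. Hydroxy and methyl are inert variety. Fixing the decoration count
# per backbone, with every decoration one heavy atom, decouples the planted
# signal from molecule size, so size-type descriptors (atom counts, MW,
# topological indices) do not proxy the label.
DECORATIONS <- c(F = "(F)", Cl = "(Cl)", Br = "(Br)", N = "(N)", S = "(S)",
                 O = "(O)", Me = "(C)")
INFORMATIVE_DECOR <- c("F", "Cl", "Br", "N", "S")
SOLVENT_POOL <- c("DMSO", "DMF", "THF", "MeOH", "EtOH", "toluene", "water", "DCM")

# one backbone: SMILES string + decoration counts (RNG state supplied by caller)
sample_backbone <- function() {
  len <- sample(3:6, 1L)
  pos <- sample.int(len, 2L)
  types <- sample(names(DECORATIONS), 2L, replace = TRUE)
  units <- rep("C", len)
  units[pos] <- paste0("C", DECORATIONS[types])
  counts <- stats::setNames(tabulate(match(types, names(DECORATIONS)),
                                     length(DECORATIONS)), names(DECORATIONS))
  list(smiles = paste(units, collapse = ""), counts = counts)
}

REACTION_TEMPLATES <- list(
  ester = function(bbA, bbB) list(
    reactants = c(paste0(bbA, "C(=O)O"), paste0(bbB, "O")),
    products = c(paste0(bbA, "C(=O)O", bbB), "O")),
  amide = function(bbA, bbB) list(
    reactants = c(paste0(bbA, "C(=O)O"), paste0(bbB, "N")),
    products = c(paste0(bbA, "C(=O)N", bbB), "O")),
  ether = function(bbA, bbB) list(
    reactants = c(paste0(bbA, "Br"), paste0(bbB, "O")),
    products = c(paste0(bbA, "O", bbB), "Br"))
)
AGENT_POOL <- c("[H+]", "OS(=O)(=O)O", "[Na+].[OH-]", NA, NA, NA)

# yields consistent with the (noisy) label under the default 65% threshold
draw_yield <- function(label) {
  if (label == 1L) stats::runif(1, 70, 100) else stats::runif(1, 0, 60)
}
# times consistent with the label under the default 12 h threshold
# (positive class = slow); unconditioned draws are log-uniform over
# [0.25 h, 96 h], mimicking the heavy "left overnight" right tail
draw_time <- function(label = NA) {
  if (is.na(label)) return(exp(stats::runif(1, log(0.25), log(96))))
  if (label == 1L) exp(stats::runif(1, log(16), log(96)))
  else exp(stats::runif(1, log(0.25), log(9)))
}

#' Generate literature-style reaction records with planted structure
#'
#' Builds reactions from a small fragment grammar (decorated alkyl backbones
#' pushed through esterification / amidation / etherification templates).
#' The noiseless label rule is a threshold on the total count of the five
#' informative decorations (F, Cl, Br, amino, thiomethyl) across both
#' substrates -- counts that surface directly as descriptor columns, so
#' informative features exist by construction. Labels are flipped with
#' probability `label_noise` (the planted Bayes error); yields (or times)
#' are then back-generated inside class-consistent ranges so that the
#' default threshold labeling reproduces the planted labels exactly.
#' Duplicates (same reaction, perturbed outcome, same class) and missing
#' condition fields are injected at the stated rates.
#'
#' @param n_reactions number of base reactions (duplicates come on top).
#' @param label_noise flip probability in `[0, 0.5)`; the planted Bayes error.
#' @param duplicate_rate per-record probability of an extra duplicate record.
#' @param missing_rate per-record probability that solvent / temperature /
#'   the non-target outcome is missing.
#' @param effect_size weight on each informative decoration count in the
#'   planted score (the rule is a deterministic threshold, so any positive
#'   value yields the same labels; it is recorded in the truth log).
#' @param target `"yield"` or `"time"`: which outcome carries the planted
#'   signal; the other is drawn unconditionally.
#' @param seed integer seed.
#' @return list with `records` (data.frame ready for [clean_reactions()])
#'   and `truth` (clean/noisy labels, scores, threshold, informative feature
#'   names, duplicate bookkeeping).
#' @export
planted_reactions <- function(n_reactions, label_noise = 0.2,
                              duplicate_rate = 0, missing_rate = 0,
                              effect_size = 1, target = c("yield", "time"),
                              seed = 1L) {
  target <- match.arg(target)
  stopifnot(n_reactions >= 2L, label_noise >= 0, label_noise < 0.5,
            duplicate_rate >= 0, duplicate_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, effect_size > 0)
  with_seed(seed, {
    draw_reaction <- function() {
      A <- sample_backbone(); B <- sample_backbone()
      tpl <- sample(names(REACTION_TEMPLATES), 1L)
      sides <- REACTION_TEMPLATES[[tpl]](A$smiles, B$smiles)
      agent <- sample(AGENT_POOL, 1L)
      list(rsmi = paste0(paste(sides$reactants, collapse = "."), ">",
                         if (is.na(agent)) "" else agent, ">",
                         paste(sides$products, collapse = ".")),
           inf = sum(A$counts[INFORMATIVE_DECOR]) + sum(B$counts[INFORMATIVE_DECOR]))
    }
    rsmi <- character(n_reactions)
    inf_count <- integer(n_reactions)
    for (i in seq_len(n_reactions)) {
      r <- draw_reaction()
      rsmi[i] <- r$rsmi; inf_count[i] <- r$inf
    }
    # base reactions must be distinct as *reactions* (canonical, agent-
    # insensitive key); independently drawn collisions are resampled so the
    # only duplicates in the output are the deliberately injected ones
    keys <- reaction_key(rsmi)
    for (round in 1:50) {
      dup <- which(duplicated(keys))
      if (length(dup) == 0L) break
      if (round == 50L) stop("could not draw ", n_reactions,
                             " distinct reactions from the grammar")
      for (i in dup) {
        r <- draw_reaction()
        rsmi[i] <- r$rsmi; inf_count[i] <- r$inf
      }
      keys[dup] <- reaction_key(rsmi[dup])
    }
    score <- effect_size * inf_count
    thr <- sort(score)[ceiling(n_reactions / 2)]  # lower-middle median
    clean <- as.integer(score > thr)
    flipped <- stats::rbinom(n_reactions, 1L, label_noise) == 1L
    noisy <- ifelse(flipped, 1L - clean, clean)

    yield <- numeric(n_reactions); time_h <- numeric(n_reactions)
    for (i in seq_len(n_reactions)) {
      if (target == "yield") {
        yield[i] <- draw_yield(noisy[i]); time_h[i] <- draw_time()
      } else {
        time_h[i] <- draw_time(noisy[i]); yield[i] <- stats::runif(1, 0, 100)
      }
    }
    solvent <- sample(SOLVENT_POOL, n_reactions, replace = TRUE)
    temp <- round(stats::runif(n_reactions, 20, 120))

    records <- data.frame(
      reaction_id = sprintf("rx%07d", seq_len(n_reactions)),
      rsmi = rsmi, yield_pct = round(yield, 1), time_h = round(time_h, 2),
      solvent = solvent, temperature_c = temp, stringsAsFactors = FALSE
    )

    # duplicates: same reaction, fresh outcome from the SAME class range,
    # so the post-dedup survivor keeps the planted class
    dup_of <- which(stats::runif(n_reactions) < duplicate_rate)
    if (length(dup_of) > 0L) {
      dups <- records[dup_of, , drop = FALSE]
      dups$reaction_id <- sprintf("rxdup%05d", seq_along(dup_of))
      for (j in seq_along(dup_of)) {
        i <- dup_of[j]
        if (target == "yield") dups$yield_pct[j] <- round(draw_yield(noisy[i]), 1)
        else dups$time_h[j] <- round(draw_time(noisy[i]), 2)
      }
      records <- rbind(records, dups)
    }

    # missing fields: conditions and the non-target outcome only
    n_all <- nrow(records)
    records$solvent[stats::runif(n_all) < missing_rate] <- NA_character_
    records$temperature_c[stats::runif(n_all) < missing_rate] <- NA_real_
    if (target == "yield") {
      records$time_h[stats::runif(n_all) < missing_rate] <- NA_real_
    } else {
      records$yield_pct[stats::runif(n_all) < missing_rate] <- NA_real_
    }
  })

  # the planted signal surfaces in the descriptor matrix both as the
  # individual heteroatom/halogen counts and as their aggregate descriptors
  # (n_halogen = F+Cl+Br, n_hetero = all non-carbon); every column that is a
  # deterministic monotone image of the planted decoration counts is listed
  informative <- as.vector(outer(c("s_", "p_"),
                                 paste0("n_", c(INFORMATIVE_DECOR,
                                                "halogen", "hetero")),
                                 paste0))
  list(
    records = records,
    truth = list(
      clean_labels = clean, noisy_labels = noisy, flipped = flipped,
      score = score, threshold = thr, bayes_error = label_noise,
      informative_features = informative,
      n_duplicates = length(dup_of), duplicate_of = dup_of,
      target = target, effect_size = effect_size, seed = seed
    )
  )
}

#' Messy raw records exercising every rejection path
#'
#' A seeded mixture of valid rows, malformed reaction SMILES, unparseable
#' structures, rows missing both outcomes, out-of-range yields, non-positive
#' times, and exact duplicates with conflicting outcomes. The manifest
#' states, by construction (not by running the cleaner), exactly how many
#' records each cleaning stage must reject or keep.
#'
#' @param n number of rows.
#' @param seed integer seed.
#' @param path optional CSV path; when given the file is written (same seed,
#'   byte-identical file) and returned in the result.
#' @return list `records` (raw data.frame), `manifest` (expected counts:
#'   per-reason rejections, clean survivors, post-dedup survivors and the
#'   per-reaction max-yield / min-time survivor values), `path`.
#' @export
messy_records <- function(n, seed = 1L, path = NULL) {
  stopifnot(n >= 1L)
  # pool of structurally distinct valid reactions (alcohol -> aldehyde
  # oxidations over distinct backbones); distinct SMILES <=> distinct keys
  # linear, 2-methyl and 2,2-dimethyl families never coincide structurally
  pool_bb <- as.vector(outer(vapply(1:12, function(k) strrep("C", k), ""),
                             c("", "C(C)", "C(C)(C)"), paste0))
  pool <- paste0(pool_bb, "CO>>", pool_bb, "C=O")
  categories <- c("valid", "malformed", "unparseable", "missing_both",
                  "bad_yield", "bad_time", "duplicate")
  weights <- c(0.55, 0.08, 0.08, 0.08, 0.06, 0.05, 0.10)
  with_seed(seed, {
    cat_draw <- sample(categories, n, replace = TRUE, prob = weights)
    # duplicates need an earlier valid row; first row is always valid
    cat_draw[1] <- "valid"
    seen_valid <- character(0)
    rows <- vector("list", n)
    used_pool <- 0L
    for (i in seq_len(n)) {
      cat_i <- cat_draw[i]
      if (cat_i == "duplicate" && length(seen_valid) == 0L) cat_i <- "valid"
      if (cat_i == "valid" && used_pool >= length(pool)) cat_i <- "duplicate"
      cat_draw[i] <- cat_i
      rsmi <- switch(cat_i,
        valid = { used_pool <- used_pool + 1L; pool[used_pool] },
        duplicate = sample(seen_valid, 1L),
        malformed = "CCO>CC=O",
        unparseable = "C1CC.XX)(>>CCO",
        missing_both = pool[1 + (i %% length(pool))],
        bad_yield = pool[1 + (i %% length(pool))],
        bad_time = pool[1 + (i %% length(pool))]
      )
      if (cat_i %in% c("valid", "duplicate")) seen_valid <- union(seen_valid, rsmi)
      rows[[i]] <- data.frame(
        reaction_id = sprintf("mx%05d", i),
        rsmi = rsmi,
        yield_pct = switch(cat_i,
          missing_both = NA_real_,
          bad_yield = round(stats::runif(1, 101, 180), 1),
          round(stats::runif(1, 1, 99), 1)),
        time_h = switch(cat_i,
          missing_both = NA_real_,
          bad_time = -round(stats::runif(1, 1, 24), 1),
          round(exp(stats::runif(1, log(0.25), log(96))), 2)),
        solvent = sample(c(SOLVENT_POOL, NA), 1L),
        temperature_c = round(stats::runif(1, 20, 120)),
        stringsAsFactors = FALSE
      )
    }
  })
  records <- do.call(rbind, rows)

  ok <- cat_draw %in% c("valid", "duplicate", "missing_both")
  clean_mask <- cat_draw %in% c("valid", "duplicate")
  clean_rsmi <- records$rsmi[clean_mask]
  surv_yield <- tapply(records$yield_pct[clean_mask], clean_rsmi, max)
  surv_time <- tapply(records$time_h[clean_mask], clean_rsmi, min)
  manifest <- list(
    n_rows = n,
    rejects = list(
      malformed_rsmi = sum(cat_draw == "malformed"),
      unparseable_smiles = sum(cat_draw == "unparseable"),
      missing_outcomes = sum(cat_draw == "missing_both"),
      yield_out_of_range = sum(cat_draw == "bad_yield"),
      nonpositive_time = sum(cat_draw == "bad_time")
    ),
    n_clean = sum(clean_mask),
    n_after_dedup = length(unique(clean_rsmi)),
    survivor_yield = as.list(surv_yield),
    survivor_time = as.list(surv_time),
    categories = cat_draw
  )
  if (!is.null(path)) {
    utils::write.csv(
      stats::setNames(records, c("id", "rsmi", "yield", "time", "solvent",
                                 "temperature")),
      path, row.names = FALSE)
  }
  list(records = records, manifest = manifest, path = path)
}
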
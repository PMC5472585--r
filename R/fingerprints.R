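# Atom-pair (AP3) fingerprints and signed reaction difference fingerprints.
#
# An AP3 feature is an (atom type, atom type, topological distance) triple
# with the shortest-path distance capped at 3 bonds; the atom type is the
# classic atom-pair typing (element, aromaticity flag, heavy-neighbor count).
# A molecule's fingerprint counts its pairs; a reaction's difference
# fingerprint is sum(reactant fps) - sum(product fps), a signed sparse count
# vector that encodes what changes over the reaction. Sparse fingerprints
# live in a native index space of capacity 800,000 and are folded to a fixed
# length by hashing indices and summing colliding entries.

AP3_NATIVE_DIM <- 800000L
AP3_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "H")
AP3_MAX_DIST <- 3L

.fp_cache <- new.env(parent = emptyenv())

new_sparse_fp <- function(index = integer(0), count = integer(0)) {
  o <- order(index)
  structure(list(index = as.integer(index[o]), count = as.integer(count[o])),
            class = "sparse_fp", D = AP3_NATIVE_DIM)
}

#' @export
print.sparse_fp <- function(x, ...) {
  cat("<sparse_fp> ", length(x$index), " non-zero entries in [0, ",
      attr(x, "D"), ")\n", sep = "")
  if (length(x$index) > 0L) {
    show <- utils::head(seq_along(x$index), 8)
    cat("  ", paste0(x$index[show], ":", x$count[show], collapse = " "),
        if (length(x$index) > 8) " ...", "\n", sep = "")
  }
  invisible(x)
}

# atom type code in [0, 16 * n_elements): (element, aromatic, min(degree, 7))
ap3_atom_types <- function(mol) {
  e <- match(mol$element, AP3_ELEMENTS)
  e[is.na(e)] <- length(AP3_ELEMENTS) + 1L   # rare-element bucket
  deg <- pmin(heavy_degree(mol), 7L)
  (e - 1L) * 16L + as.integer(mol$aromatic) * 8L + deg
}

AP3_TYPE_SPACE <- 16L * (length(AP3_ELEMENTS) + 1L)

# native index of one (type, type, distance) triple (0-based)
ap3_pair_index <- function(t1, t2, d) {
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  (lo * AP3_TYPE_SPACE + hi) * AP3_MAX_DIST + (d - 1L)
}

#' Atom-pair fingerprint of one molecule (max path length 3)
#'
#' One count per (atom type, atom type, shortest-path distance <= 3) triple
#' over all heavy-atom pairs. Single-atom molecules have no pairs and yield
#' an empty fingerprint.
#'
#' @param mol a `molgraph` or single SMILES string.
#' @return a `sparse_fp`.
#' @export
ap3_fingerprint <- function(mol) {
  if (!inherits(mol, "molgraph")) mol <- molgraph(mol)
  n <- mol$n_atoms
  if (n < 2L) return(new_sparse_fp())
  A <- matrix(0L, n, n)
  A[cbind(mol$bond_a, mol$bond_b)] <- 1L
  A[cbind(mol$bond_b, mol$bond_a)] <- 1L
  A2 <- A %*% A
  A3 <- A2 %*% A
  Dm <- matrix(0L, n, n)
  Dm[A3 > 0L] <- 3L
  Dm[A2 > 0L] <- 2L
  Dm[A > 0L] <- 1L
  diag(Dm) <- 0L
  t <- ap3_atom_types(mol)
  iu <- which(upper.tri(Dm) & Dm > 0L, arr.ind = TRUE)
  if (nrow(iu) == 0L) return(new_sparse_fp())
  idx <- ap3_pair_index(t[iu[, 1]], t[iu[, 2]], Dm[iu])
  tab <- table(idx)
  new_sparse_fp(as.integer(names(tab)), as.integer(tab))
}

# signed sum of sparse fingerprints: sum(w[i] * fps[[i]])
sparse_fp_combine <- function(fps, w = rep(1L, length(fps))) {
  idx <- unlist(lapply(fps, `[[`, "index"), use.names = FALSE)
  cnt <- unlist(mapply(function(f, wi) f$count * wi, fps, w,
                       SIMPLIFY = FALSE), use.names = FALSE)
  if (length(idx) == 0L) return(new_sparse_fp())
  s <- rowsum(cnt, idx)
  keep <- s[, 1] != 0
  new_sparse_fp(as.integer(rownames(s))[keep], s[keep, 1])
}

# memoized per-molecule AP3 (keyed on raw SMILES)
ap3_cached <- function(smiles) {
  lapply(smiles, function(s) {
    if (!exists(s, envir = .fp_cache)) {
      assign(s, ap3_fingerprint(molgraph(s)), envir = .fp_cache)
    }
    get(s, envir = .fp_cache)
  })
}

#' Signed reaction difference fingerprint
#'
#' `sum over reactants of ap3 - sum over products of ap3`, with zero entries
#' dropped. Agents are excluded from both sums. An identity reaction maps to
#' the empty fingerprint, and swapping the sides negates every entry.
#'
#' @param reaction a reaction SMILES string, or a list with character vectors
#'   `reactants` and `products`.
#' @return a `sparse_fp` with signed counts.
#' @export
reaction_fingerprint <- function(reaction) {
  if (is.character(reaction)) {
    sides <- split_rsmi(reaction)
    if (is.null(sides) || length(sides$reactants) == 0L || length(sides$products) == 0L) {
      stop("invalid reaction SMILES: ", reaction)
    }
  } else {
    sides <- reaction
    stopifnot(is.character(sides$reactants), is.character(sides$products))
  }
  fps <- ap3_cached(c(sides$reactants, sides$products))
  w <- c(rep(1L, length(sides$reactants)), rep(-1L, length(sides$products)))
  sparse_fp_combine(fps, w)
}

#' Fold a sparse fingerprint to fixed length
#'
#' Hashes every native index to `[0, L)` and sums colliding entries; the
#' signed total is conserved. The default hash is index modulo L; `"mix"`
#' applies a Knuth multiplicative scramble first (both deterministic).
#'
#' @param fp a `sparse_fp`.
#' @param L folded length (default 256).
#' @param hash `"modulo"` or `"mix"`.
#' @return a `folded_fp`: integer vector of length `L`.
#' @export
fold_fingerprint <- function(fp, L = 256L, hash = c("modulo", "mix")) {
  stopifnot(inherits(fp, "sparse_fp"))
  hash <- match.arg(hash)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("folded length L must be a positive integer")
  v <- integer(L)
  if (length(fp$index) > 0L) {
    h <- if (hash == "modulo") fp$index %% L else {
      (fp$index * 2654435761) %% 4294967296 %% L
    }
    s <- rowsum(fp$count, h)
    v[as.integer(rownames(s)) + 1L] <- s[, 1]
  }
  structure(v, class = "folded_fp", L = L, hash = hash)
}

#' @export
print.folded_fp <- function(x, ...) {
  cat("<folded_fp> length ", attr(x, "L"), ", ", sum(x != 0),
      " non-zero, hash=", attr(x, "hash"), "\n", sep = "")
  invisible(x)
}

#' Folded reaction fingerprint matrix for a record set
#'
#' @param records clean record data.frame with an `rsmi` column.
#' @param L folded length.
#' @param hash hashing strategy, see [fold_fingerprint()].
#' @return integer matrix `nrow(records) x L` with columns `fp_1..fp_L`,
#'   rownames = reaction ids, and a `family` attribute of "fingerprint".
#' @export
fingerprint_matrix <- function(records, L = 256L, hash = "modulo") {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  X <- matrix(0L, nrow(records), L)
  for (i in seq_len(nrow(records))) {
    X[i, ] <- as.integer(fold_fingerprint(reaction_fingerprint(records$rsmi[i]),
                                          L, hash))
  }
  colnames(X) <- paste0("fp_", seq_len(L))
  rownames(X) <- records$reaction_id
  attr(X, "family") <- rep("fingerprint", L)
  X
}
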
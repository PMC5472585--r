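# Independent oracles used across the test suite. Each reimplements the
# quantity under test from first principles along a different algorithmic
# path (Floyd-Warshall instead of BFS/matrix powers, exhaustive subset
# enumeration instead of backtracking, a plain double loop instead of the
# blocked C++ kernel), so agreement is evidence, not tautology.

# all-pairs shortest path by Floyd-Warshall on the bond graph
fw_distances <- function(mol) {
  n <- mol$n_atoms
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (e in seq_along(mol$bond_a)) {
    D[mol$bond_a[e], mol$bond_b[e]] <- 1
    D[mol$bond_b[e], mol$bond_a[e]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# brute-force AP3 enumeration: every unordered atom pair at distance 1..3,
# typed as (element, aromatic, min(heavy degree, 7)) exactly as documented
brute_ap3 <- function(mol) {
  n <- mol$n_atoms
  if (n < 2) return(stats::setNames(integer(0), character(0)))
  D <- fw_distances(mol)
  deg <- integer(n)
  for (e in seq_along(mol$bond_a)) {
    deg[mol$bond_a[e]] <- deg[mol$bond_a[e]] + 1L
    deg[mol$bond_b[e]] <- deg[mol$bond_b[e]] + 1L
  }
  elems <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "H")
  tcode <- function(i) {
    e <- match(mol$element[i], elems)
    if (is.na(e)) e <- length(elems) + 1L
    (e - 1L) * 16L + as.integer(mol$aromatic[i]) * 8L + min(deg[i], 7L)
  }
  acc <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- D[i, j]
    if (is.finite(d) && d >= 1 && d <= 3) {
      t1 <- tcode(i); t2 <- tcode(j)
      idx <- (min(t1, t2) * (16L * 13L) + max(t1, t2)) * 3L + (d - 1L)
      acc <- c(acc, idx)
    }
  }
  tab <- table(acc)
  stats::setNames(as.integer(tab), names(tab))
}

# exhaustive maximum connected common induced subgraph size for molecules
# with few atoms: enumerate every connected induced subgraph of A and test
# for an induced embedding in B by permutation backtracking
brute_mcs_size <- function(molA, molB) {
  btm <- function(m) {
    bm <- matrix("", m$n_atoms, m$n_atoms)
    for (e in seq_along(m$bond_a)) {
      bm[m$bond_a[e], m$bond_b[e]] <- m$bond_type[e]
      bm[m$bond_b[e], m$bond_a[e]] <- m$bond_type[e]
    }
    bm
  }
  btA <- btm(molA); btB <- btm(molB)
  symA <- paste0(molA$element, molA$aromatic)
  symB <- paste0(molB$element, molB$aromatic)
  nA <- molA$n_atoms; nB <- molB$n_atoms
  connected <- function(S, bt) {
    if (length(S) <= 1) return(TRUE)
    seen <- S[1]; frontier <- S[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(S[sapply(S, function(v) any(bt[v, frontier] != ""))], seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(S)
  }
  embeds <- function(S) {
    k <- length(S)
    recurse <- function(pos, map, used) {
      if (pos > k) return(TRUE)
      a <- S[pos]
      for (b in seq_len(nB)) {
        if (used[b] || symB[b] != symA[a]) next
        ok <- TRUE
        if (pos > 1) for (q in seq_len(pos - 1)) {
          if (btA[a, S[q]] != btB[b, map[q]]) { ok <- FALSE; break }
        }
        if (ok) {
          used[b] <- TRUE
          if (recurse(pos + 1, c(map, b), used)) return(TRUE)
          used[b] <- FALSE
        }
      }
      FALSE
    }
    recurse(1, integer(0), rep(FALSE, nB))
  }
  best <- 0L
  for (mask in seq_len(2^nA - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(nA) - 1)) > 0)
    if (length(S) <= best) next
    if (!connected(S, btA)) next
    if (embeds(S)) best <- length(S)
  }
  best
}

# plain-R leave-one-out k-NN with the documented deterministic tie rules
r_loo_knn_error <- function(X, y, k = 1, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) {
    mu <- colMeans(X); s <- apply(X, 2, sd); s[s == 0 | !is.finite(s)] <- 1
    X <- sweep(sweep(X, 2, mu), 2, s, "/")
  }
  n <- nrow(X)
  pred <- integer(n)
  lev <- sort(unique(y))
  yi <- match(y, lev) - 1L
  for (i in seq_len(n)) {
    d2 <- colSums((t(X) - X[i, ])^2)
    d2[i] <- Inf
    ord <- order(d2, seq_len(n))  # distance ties -> smaller row index
    nb <- yi[ord[seq_len(k)]]
    votes <- tabulate(nb + 1L, nbins = length(lev))
    pred[i] <- which.max(votes) - 1L  # vote ties -> smaller class
  }
  mean(pred != yi)
}

# a small fixture corpus from the package's own reaction grammar plus a few
# classic structures; every molecule parses and has <= 12 heavy atoms
fixture_smiles <- function() {
  c("C", "CC", "CCC", "CCCCC", "CC(C)C", "CCO", "OCC", "CC=O", "CC(=O)O",
    "CC(=O)OCC", "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    "c1ccncc1", "c1ccoc1", "CC(F)CC", "CC(Cl)C", "BrCCBr", "C#N", "CC#N",
    "CCNCC", "CSC", "C=CC=C", "C1CCCCC1", "C1CCNCC1", "[He]", "[H+]", "O")
}
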
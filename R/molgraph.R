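# Heavy-atom molecular graphs.
#
# A `molgraph` is the package's working representation of one molecule:
# elements, aromatic flags (an atom is aromatic iff it sits on a perceived
# aromatic bond), and a typed bond list. Hydrogens are implicit; descriptor
# work that needs them (MW, HBD, ...) goes through OpenBabel properties.

new_molgraph <- function(g, smiles = NA_character_, cansmi = NA_character_) {
  structure(
    list(n_atoms = g$n_atoms, element = g$element, aromatic = g$aromatic,
         bond_a = g$bond_a, bond_b = g$bond_b, bond_type = g$bond_type,
         smiles = smiles, cansmi = cansmi),
    class = "molgraph"
  )
}

#' Construct a molecular graph from a single SMILES
#'
#' @param smiles one SMILES string.
#' @return a `molgraph` object.
#' @export
molgraph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  m <- parse_molecules(smiles)[[1]]
  if (is.null(m)) stop("unparseable SMILES: ", smiles)
  m
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", x$n_atoms, " (", sum(x$aromatic), " aromatic), bonds: ",
      length(x$bond_a), "\n", sep = "")
  if (!is.na(x$cansmi)) cat("  canonical: ", x$cansmi, "\n", sep = "")
  invisible(x)
}

# neighbor (adjacency) list; index i -> integer vector of neighbors
adjacency_list <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  for (i in seq_len(mol$n_atoms)) adj[[i]] <- integer(0)
  for (e in seq_along(mol$bond_a)) {
    a <- mol$bond_a[e]; b <- mol$bond_b[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

heavy_degree <- function(mol) {
  d <- integer(mol$n_atoms)
  t <- tabulate(c(mol$bond_a, mol$bond_b), nbins = mol$n_atoms)
  d + t
}

# n x n bond-type matrix: "" where no bond, else the bond type code
bond_type_matrix <- function(mol) {
  m <- matrix("", mol$n_atoms, mol$n_atoms)
  for (e in seq_along(mol$bond_a)) {
    m[mol$bond_a[e], mol$bond_b[e]] <- mol$bond_type[e]
    m[mol$bond_b[e], mol$bond_a[e]] <- mol$bond_type[e]
  }
  m
}

# All-pairs topological distances (Inf where disconnected): simultaneous
# BFS over all sources via boolean matrix products -- fast for the small
# graphs molecules are.
topo_distances <- function(mol) {
  n <- mol$n_atoms
  A <- matrix(0, n, n)
  if (length(mol$bond_a) > 0L) {
    A[cbind(mol$bond_a, mol$bond_b)] <- 1
    A[cbind(mol$bond_b, mol$bond_a)] <- 1
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n)
  d <- 0
  repeat {
    d <- d + 1L
    reach <- (reach %*% A) > 0
    new <- reach & is.infinite(D)
    if (!any(new) || d > n) break
    D[new] <- d
  }
  D
}

# Connected components as an integer membership vector.
graph_components <- function(n, a, b) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (e in seq_along(a)) {
    adj[[a[e]]] <- c(adj[[a[e]]], b[e])
    adj[[b[e]]] <- c(adj[[b[e]]], a[e])
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    frontier <- s; comp[s] <- cid
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  comp
}

# Logical vector over bonds: is the bond part of a ring? (= not a bridge;
# Tarjan's low-link DFS). Acyclic graphs short-circuit.
ring_bond_flags <- function(mol) {
  n <- mol$n_atoms
  nb <- length(mol$bond_a)
  flags <- logical(nb)
  if (nb == 0L) return(flags)
  n_comp <- max(graph_components(n, mol$bond_a, mol$bond_b))
  if (nb - n + n_comp == 0L) return(flags)  # forest: every bond is a bridge
  adj <- vector("list", n)
  for (e in seq_len(nb)) {
    adj[[mol$bond_a[e]]] <- rbind(adj[[mol$bond_a[e]]], c(mol$bond_b[e], e))
    adj[[mol$bond_b[e]]] <- rbind(adj[[mol$bond_b[e]]], c(mol$bond_a[e], e))
  }
  disc <- integer(n); low <- integer(n)
  timer <- 0L
  is_bridge <- logical(nb)
  dfs <- function(u, pe) {
    timer <<- timer + 1L
    disc[u] <<- timer; low[u] <<- timer
    if (is.null(adj[[u]])) return(invisible())
    for (r in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][r, 1]; e <- adj[[u]][r, 2]
      if (e == pe) next
      if (disc[v] == 0L) {
        dfs(v, e)
        low[u] <<- min(low[u], low[v])
        if (low[v] > disc[u]) is_bridge[e] <<- TRUE
      } else low[u] <<- min(low[u], disc[v])
    }
  }
  for (s in seq_len(n)) if (disc[s] == 0L) dfs(s, 0L)
  !is_bridge
}
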
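# Whole-molecule descriptors and reaction-level descriptor features.
#
# Each molecule gets a fixed-width descriptor vector combining OpenBabel
# physicochemical properties (MW, logP, TPSA, MR, H-bond counts) with graph
# descriptors computed from the heavy-atom molgraph (atom/bond/ring counts,
# aromaticity, degree statistics, and classic topological indices: Wiener,
# Zagreb, Randic, diameter). A reaction row concatenates the elementwise SUM
# of its reactant vectors (substrate block), the sum of its product vectors
# (product block), and the experimental conditions (solvent code,
# temperature). Agents contribute no descriptor block.

PHYSCHEM_DESCRIPTORS <- c("MW", "logP", "TPSA", "MR", "HBD", "HBA1")

GRAPH_DESCRIPTORS <- c(
  "n_atoms", "n_bonds", "n_C", "n_N", "n_O", "n_S", "n_P",
  "n_F", "n_Cl", "n_Br", "n_I", "n_halogen", "n_hetero",
  "n_rings", "n_aromatic_atoms", "n_aromatic_bonds", "n_aromatic_rings",
  "frac_aromatic", "n_single", "n_double", "n_triple", "n_rotatable",
  "max_degree", "mean_degree", "n_terminal", "n_branched",
  "zagreb", "randic", "wiener", "diameter", "mean_dist"
)

#' The default molecular descriptor list
#'
#' @return character vector of descriptor names understood by
#'   [molecule_descriptors()].
#' @export
default_descriptors <- function() c(PHYSCHEM_DESCRIPTORS, GRAPH_DESCRIPTORS)

#' Read a descriptor list from a plain-text config file (one name per line)
#'
#' @param path file with one descriptor name per line; `#` comments allowed.
#' @return character vector of descriptor names.
#' @export
read_descriptor_config <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unknown <- setdiff(x, default_descriptors())
  if (length(unknown) > 0L) {
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "))
  }
  x
}

# All graph-derived descriptors for one molgraph, as a named numeric vector.
graph_descriptors <- function(mol) {
  n <- mol$n_atoms
  deg <- heavy_degree(mol)
  el <- mol$element
  bt <- mol$bond_type
  nb <- length(bt)
  n_hal <- sum(el %in% c("F", "Cl", "Br", "I"))
  comp <- graph_components(n, mol$bond_a, mol$bond_b)
  n_comp <- max(comp)
  ar_e <- bt == "ar"
  n_ar_atoms <- sum(mol$aromatic)
  ar_comp <- if (any(ar_e)) {
    sub <- unique(c(mol$bond_a[ar_e], mol$bond_b[ar_e]))
    remap <- match(c(mol$bond_a[ar_e], mol$bond_b[ar_e]), sub)
    k <- sum(ar_e)
    max(graph_components(length(sub), remap[seq_len(k)], remap[k + seq_len(k)]))
  } else 0L
  ring_e <- ring_bond_flags(mol)
  rot <- sum(bt == "1" & !ring_e &
               deg[mol$bond_a] >= 2L & deg[mol$bond_b] >= 2L)
  D <- topo_distances(mol)
  fin <- D[upper.tri(D)]
  fin <- fin[is.finite(fin)]
  c(
    n_atoms = n, n_bonds = nb,
    n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
    n_S = sum(el == "S"), n_P = sum(el == "P"),
    n_F = sum(el == "F"), n_Cl = sum(el == "Cl"), n_Br = sum(el == "Br"),
    n_I = sum(el == "I"), n_halogen = n_hal,
    n_hetero = sum(!el %in% c("C", "H")),
    n_rings = nb - n + n_comp,
    n_aromatic_atoms = n_ar_atoms, n_aromatic_bonds = sum(ar_e),
    n_aromatic_rings = if (ar_comp > 0L) sum(ar_e) - n_ar_atoms + ar_comp else 0L,
    frac_aromatic = if (n > 0L) n_ar_atoms / n else 0,
    n_single = sum(bt == "1"), n_double = sum(bt == "2"),
    n_triple = sum(bt == "3"), n_rotatable = rot,
    max_degree = if (n > 0L) max(deg) else 0,
    mean_degree = mean(deg),
    n_terminal = sum(deg == 1L), n_branched = sum(deg >= 3L),
    zagreb = sum(deg^2),
    randic = if (nb > 0L) sum(1 / sqrt(deg[mol$bond_a] * deg[mol$bond_b])) else 0,
    wiener = sum(fin),
    diameter = if (length(fin) > 0L) max(fin) else 0,
    mean_dist = if (length(fin) > 0L) mean(fin) else 0
  )
}

#' Descriptor vectors for a batch of molecules
#'
#' @param smiles character vector of SMILES (duplicates are computed once).
#' @param descriptors descriptor names; default [default_descriptors()].
#' @return numeric matrix, one row per input SMILES, with a `n_failed`
#'   attribute counting per-column sentinel substitutions. Rows for
#'   unparseable SMILES are all-NA.
#' @export
descriptor_table <- function(smiles, descriptors = default_descriptors()) {
  stopifnot(is.character(smiles))
  uniq <- unique(smiles)
  mols <- parse_molecules(uniq)
  ok <- !vapply(mols, is.null, FALSE)
  gnames <- intersect(descriptors, GRAPH_DESCRIPTORS)
  pnames <- intersect(descriptors, PHYSCHEM_DESCRIPTORS)
  U <- matrix(NA_real_, length(uniq), length(descriptors),
              dimnames = list(NULL, descriptors))
  if (length(pnames) > 0L && any(ok)) {
    U[ok, pnames] <- as.matrix(ob_properties(uniq[ok], pnames))
  }
  if (length(gnames) > 0L) {
    for (i in which(ok)) U[i, gnames] <- graph_descriptors(mols[[i]])[gnames]
  }
  # non-finite / failed entries -> 0 sentinel, tallied per column
  failed <- matrix(FALSE, length(uniq), length(descriptors))
  failed[ok, ] <- !is.finite(U[ok, , drop = FALSE])
  U[ok, ][!is.finite(U[ok, , drop = FALSE])] <- 0
  out <- U[match(smiles, uniq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_failed") <- colSums(failed[match(smiles, uniq), , drop = FALSE])
  out
}

#' Descriptor vector for one molecule
#'
#' Deterministic: the same molecule (by canonical SMILES) always maps to the
#' identical vector, whatever SMILES spelling is supplied.
#'
#' @param mol a `molgraph` or a single SMILES string.
#' @inheritParams descriptor_table
#' @return named numeric vector.
#' @export
molecule_descriptors <- function(mol, descriptors = default_descriptors()) {
  smi <- if (inherits(mol, "molgraph")) mol$smiles else mol
  v <- descriptor_table(smi, descriptors)[1, ]
  if (all(is.na(v))) stop("unparseable SMILES: ", smi)
  v
}

#' Build a solvent vocabulary from training records
#'
#' Maps each distinct solvent string to an integer code; unseen or missing
#' solvents encode as the reserved code 0 ("unknown"). Build the vocabulary
#' on training data only to avoid test-set leakage.
#'
#' @param solvents character vector of solvent strings (NA allowed).
#' @return named integer vector (codes), class `solvent_vocab`.
#' @export
build_solvent_vocab <- function(solvents) {
  lv <- sort(unique(solvents[!is.na(solvents)]))
  structure(stats::setNames(seq_along(lv), lv), class = "solvent_vocab")
}

encode_solvent <- function(solvents, vocab) {
  idx <- vocab[solvents]
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Reaction-level descriptor features
#'
#' One row per reaction: substrate block = elementwise sum of reactant
#' descriptor vectors, product block = sum over products, then the encoded
#' conditions. Missing temperature is imputed with the (training) median.
#'
#' @param records clean record data.frame (`rsmi` plus condition columns).
#' @param descriptors descriptor names.
#' @param solvent_vocab a [build_solvent_vocab()] result; built from
#'   `records` when NULL.
#' @param temperature_impute value for missing temperatures; median of the
#'   observed temperatures in `records` when NULL.
#' @return numeric matrix with columns `s_<name>..., p_<name>..., solvent,
#'   temperature`, a `family` attribute tagging each column
#'   (descriptor/condition) and rownames = reaction ids.
#' @export
reaction_features <- function(records, descriptors = default_descriptors(),
                              solvent_vocab = NULL, temperature_impute = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  sides <- lapply(records$rsmi, split_rsmi)
  bad <- vapply(sides, function(s) {
    is.null(s) || length(s$reactants) == 0L || length(s$products) == 0L
  }, FALSE)
  if (any(bad)) stop("invalid reaction SMILES at row(s): ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  all_smi <- unique(unlist(lapply(sides, function(s) c(s$reactants, s$products)),
                           use.names = FALSE))
  tab <- descriptor_table(all_smi, descriptors)
  if (anyNA(tab)) {
    stop("unparseable component SMILES; run clean_reactions() first")
  }
  d <- length(descriptors)
  n <- nrow(records)
  sub_block <- matrix(0, n, d)
  prod_block <- matrix(0, n, d)
  for (i in seq_len(n)) {
    ri <- match(sides[[i]]$reactants, all_smi)
    pi <- match(sides[[i]]$products, all_smi)
    sub_block[i, ] <- .colSums(tab[ri, , drop = FALSE], length(ri), d)
    prod_block[i, ] <- .colSums(tab[pi, , drop = FALSE], length(pi), d)
  }
  vocab <- solvent_vocab %||% build_solvent_vocab(records$solvent)
  timp <- temperature_impute %||% stats::median(records$temperature_c, na.rm = TRUE)
  if (!is.finite(timp)) timp <- 25  # no temperatures anywhere: ambient
  temp <- ifelse(is.na(records$temperature_c), timp, records$temperature_c)
  X <- cbind(sub_block, prod_block,
             solvent = encode_solvent(records$solvent, vocab),
             temperature = temp)
  colnames(X) <- c(paste0("s_", descriptors), paste0("p_", descriptors),
                   "solvent", "temperature")
  rownames(X) <- records$reaction_id
  attr(X, "family") <- c(rep("descriptor", 2L * d), "condition", "condition")
  X
}
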
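# Chemical-linguistic descriptors (CLDs).
#
# A CLD is a frequently recurring maximum common substructure (MCS) mined
# over sampled molecule pairs -- by analogy with frequent word fragments in
# natural language, these "chemical words" capture mid-scale structural
# motifs (ring arrangements, decorated chains) that whole-molecule
# descriptors and isolated functional groups miss. The MCS here is the
# largest CONNECTED common induced substructure under strict matching:
# element, aromaticity and bond order (aromatic distinguished from single/
# double) must all agree. Mined patterns are canonicalized, ranked by
# frequency, and used as binary presence features over a reaction's
# molecules.

atom_symbols <- function(g) paste0(g$element, ifelse(g$aromatic, ":ar", ""))

# induced subgraph of mol on atom set `atoms` (kept in the given order)
induce_subgraph <- function(mol, atoms) {
  keep <- mol$bond_a %in% atoms & mol$bond_b %in% atoms
  list(n_atoms = length(atoms),
       element = mol$element[atoms],
       aromatic = mol$aromatic[atoms],
       bond_a = match(mol$bond_a[keep], atoms),
       bond_b = match(mol$bond_b[keep], atoms),
       bond_type = mol$bond_type[keep])
}

## ---- canonical labeling (iterative refinement + individualization) ----

refine_labels <- function(g, labels) {
  nbrs <- vector("list", g$n_atoms)
  for (i in seq_len(g$n_atoms)) nbrs[[i]] <- character(0)
  for (e in seq_along(g$bond_a)) {
    a <- g$bond_a[e]; b <- g$bond_b[e]; t <- g$bond_type[e]
    nbrs[[a]] <- c(nbrs[[a]], paste0(t, "~", labels[b]))
    nbrs[[b]] <- c(nbrs[[b]], paste0(t, "~", labels[a]))
  }
  repeat {
    sig <- vapply(seq_len(g$n_atoms), function(i) {
      paste(labels[i], paste(sort(nbrs[[i]]), collapse = ","), sep = "|")
    }, "")
    new_labels <- sprintf("%03d", match(sig, sort(unique(sig))))
    if (identical(split(seq_along(labels), labels),
                  split(seq_along(new_labels), new_labels))) {
      return(new_labels)
    }
    labels <- new_labels
    for (i in seq_len(g$n_atoms)) nbrs[[i]] <- character(0)
    for (e in seq_along(g$bond_a)) {
      a <- g$bond_a[e]; b <- g$bond_b[e]; t <- g$bond_type[e]
      nbrs[[a]] <- c(nbrs[[a]], paste0(t, "~", labels[b]))
      nbrs[[b]] <- c(nbrs[[b]], paste0(t, "~", labels[a]))
    }
  }
}

graph_certificate <- function(g, ranks) {
  ord <- order(ranks)
  pos <- integer(g$n_atoms); pos[ord] <- seq_len(g$n_atoms)
  atoms <- paste(atom_symbols(g)[ord], collapse = ";")
  if (length(g$bond_a) > 0L) {
    ea <- pmin(pos[g$bond_a], pos[g$bond_b])
    eb <- pmax(pos[g$bond_a], pos[g$bond_b])
    es <- paste0(ea, "-", eb, "-", g$bond_type)
    edges <- paste(sort(es), collapse = ";")
  } else edges <- ""
  paste(atoms, edges, sep = "||")
}

# canonical ranks: smallest certificate over individualization branches
canonical_ranks <- function(g, labels = NULL) {
  labels <- refine_labels(g, labels %||% atom_symbols(g))
  tab <- table(labels)
  if (all(tab == 1L)) {
    ranks <- match(labels, sort(labels))
    return(list(ranks = ranks, cert = graph_certificate(g, ranks)))
  }
  cell_label <- names(tab)[tab > 1L][1]
  members <- which(labels == cell_label)
  best <- NULL
  for (m in members) {
    lab2 <- labels
    lab2[m] <- paste0(lab2[m], "*")
    cand <- canonical_ranks(g, lab2)
    if (is.null(best) || cand$cert < best$cert) best <- cand
  }
  best
}

## ---- pattern string writer / reader ----

PATTERN_BOND_SYMBOL <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")

pattern_atom_token <- function(element, aromatic) {
  if (aromatic) tolower(element) else element
}

# SMILES/SMARTS-like linear notation with explicit bond symbols
# (-, =, #, : for aromatic) and ring-closure digits; deterministic given
# canonical ranks.
pattern_string <- function(g, ranks) {
  n <- g$n_atoms
  if (n == 0L) return("")
  bt <- matrix("", n, n)
  for (e in seq_along(g$bond_a)) {
    bt[g$bond_a[e], g$bond_b[e]] <- g$bond_type[e]
    bt[g$bond_b[e], g$bond_a[e]] <- g$bond_type[e]
  }
  nbr <- lapply(seq_len(n), function(i) {
    v <- which(bt[i, ] != "")
    v[order(ranks[v])]
  })
  visited <- rep(FALSE, n)
  tree_child <- vector("list", n)
  closures <- vector("list", n)   # list of c(digit, bond) per atom
  next_digit <- 0L
  open_edges <- new.env(parent = emptyenv())
  root <- which(ranks == min(ranks))[1]
  # pass 1: iterative DFS fixing tree edges and closure digits
  stack <- list(list(atom = root, parent = 0L))
  visited[root] <- TRUE
  order_visit <- integer(0)
  dfs <- function(u, parent) {
    order_visit <<- c(order_visit, u)
    for (v in nbr[[u]]) {
      if (v == parent) next
      ekey <- paste(min(u, v), max(u, v))
      if (visited[v]) {
        if (is.null(open_edges[[ekey]])) {
          next_digit <<- next_digit + 1L
          open_edges[[ekey]] <- next_digit
          closures[[u]] <<- c(closures[[u]], list(c(next_digit, bt[u, v])))
          closures[[v]] <<- c(closures[[v]], list(c(next_digit, bt[u, v])))
        }
      } else {
        visited[v] <<- TRUE
        tree_child[[u]] <<- c(tree_child[[u]], v)
        dfs(v, u)
      }
    }
  }
  dfs(root, 0L)
  emit <- function(u, bond_in) {
    tok <- if (nzchar(bond_in)) PATTERN_BOND_SYMBOL[[bond_in]] else ""
    tok <- paste0(tok, pattern_atom_token(g$element[u], g$aromatic[u]))
    for (cl in closures[[u]]) {
      d <- as.integer(cl[1])
      dd <- if (d <= 9) as.character(d) else paste0("%", d)
      tok <- paste0(tok, PATTERN_BOND_SYMBOL[[cl[2]]], dd)
    }
    ch <- tree_child[[u]]
    if (length(ch) > 0L) {
      parts <- vapply(ch, function(v) emit(v, bt[u, v]), "")
      if (length(parts) > 1L) {
        tok <- paste0(tok, paste0("(", parts[-length(parts)], ")", collapse = ""))
      }
      tok <- paste0(tok, parts[length(parts)])
    }
    tok
  }
  emit(root, "")
}

PATTERN_ELEMENTS <- c("Cl", "Br", "Si", "B", "C", "N", "O", "P", "S", "F", "I", "H")

#' Parse a CLD pattern string back into a pattern graph
#'
#' Reads the linear notation emitted by the vocabulary writer: element
#' symbols (lowercase = aromatic), explicit bond symbols `-`, `=`, `#`, `:`,
#' parenthesised branches and ring-closure digits (`%nn` above 9).
#'
#' @param s a pattern string.
#' @return a pattern graph (atom/bond lists as in a `molgraph`).
#' @export
parse_pattern <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  element <- character(0); aromatic <- logical(0)
  bond_a <- integer(0); bond_b <- integer(0); bond_type <- character(0)
  bond_of <- c("-" = "1", "=" = "2", "#" = "3", ":" = "ar")
  stack <- integer(0)
  prev <- 0L
  pend_bond <- ""
  open_ring <- list()
  i <- 1L
  add_bond <- function(a, b, t) {
    bond_a <<- c(bond_a, a); bond_b <<- c(bond_b, b)
    bond_type <<- c(bond_type, if (nzchar(t)) t else "1")
  }
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% names(bond_of)) {
      pend_bond <- bond_of[[ch]]; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        d <- as.integer(substr(s, i + 1L, i + 2L)); i <- i + 3L
      } else {
        d <- as.integer(ch); i <- i + 1L
      }
      key <- as.character(d)
      if (is.null(open_ring[[key]])) {
        open_ring[[key]] <- c(prev, pend_bond)
      } else {
        add_bond(as.integer(open_ring[[key]][1]), prev,
                 if (nzchar(pend_bond)) pend_bond else open_ring[[key]][2])
        open_ring[[key]] <- NULL
      }
      pend_bond <- ""
    } else {
      two <- substr(s, i, i + 1L)
      el <- if (two %in% PATTERN_ELEMENTS) two else {
        one <- toupper(ch)
        if (!(one %in% PATTERN_ELEMENTS || toupper(two) %in% PATTERN_ELEMENTS)) {
          stop("cannot parse pattern at position ", i, ": ", s)
        }
        if (toupper(two) %in% PATTERN_ELEMENTS && tolower(two) == two) toupper(two) else one
      }
      is_ar <- substr(s, i, i) == tolower(substr(s, i, i)) &&
        substr(s, i, i) != toupper(substr(s, i, i))
      i <- i + nchar(el)
      element <- c(element, el); aromatic <- c(aromatic, is_ar)
      a <- length(element)
      if (prev > 0L) add_bond(prev, a, if (nzchar(pend_bond)) pend_bond else
        if (is_ar && aromatic[prev]) "ar" else "1")
      pend_bond <- ""
      prev <- a
    }
  }
  list(n_atoms = length(element), element = element, aromatic = aromatic,
       bond_a = bond_a, bond_b = bond_b, bond_type = bond_type)
}

## ---- maximum common substructure ----

new_substructure <- function(g, approximate = FALSE) {
  cr <- canonical_ranks(g)
  structure(list(pattern = pattern_string(g, cr$ranks),
                 certificate = cr$cert,
                 atom_count = g$n_atoms,
                 bond_count = length(g$bond_a),
                 graph = g,
                 approximate = approximate),
            class = "substructure")
}

#' @export
print.substructure <- function(x, ...) {
  cat("<substructure> ", x$pattern, " (", x$atom_count, " atoms, ",
      x$bond_count, " bonds", if (x$approximate) ", approximate", ")\n", sep = "")
  invisible(x)
}

#' Maximum common substructure of two molecules
#'
#' Finds a largest connected common induced substructure: atoms must agree on
#' element and aromaticity, bonds on order (aromatic distinct from single and
#' double). Size ties are broken by bond count, then by lexicographic pattern
#' string, so the result is deterministic. Returns `NULL` when the best
#' common substructure is smaller than `min_size` atoms.
#'
#' @param molA,molB `molgraph` objects or SMILES strings.
#' @param min_size minimum number of atoms for a reportable substructure.
#' @param timeout_s soft time budget; on expiry the best substructure found
#'   so far is returned flagged `approximate = TRUE`.
#' @return a `substructure` or `NULL`.
#' @export
mcs <- function(molA, molB, min_size = 3L, timeout_s = 10) {
  if (!inherits(molA, "molgraph")) molA <- molgraph(molA)
  if (!inherits(molB, "molgraph")) molB <- molgraph(molB)
  nA <- molA$n_atoms; nB <- molB$n_atoms
  btA <- bond_type_matrix(molA); btB <- bond_type_matrix(molB)
  symA <- atom_symbols(molA); symB <- atom_symbols(molB)
  adjA <- adjacency_list(molA)
  compat <- outer(symA, symB, "==")
  best_map <- NULL; best_size <- 0L; best_bonds <- -1L; best_pat <- NULL
  timed_out <- FALSE
  t0 <- Sys.time()
  nodes <- 0L

  count_bonds <- function(mapA) {
    atoms <- which(mapA > 0L)
    if (length(atoms) < 2L) return(0L)
    sum(btA[atoms, atoms][upper.tri(btA[atoms, atoms])] != "")
  }
  consider <- function(mapA) {
    size <- sum(mapA > 0L)
    nb <- count_bonds(mapA)
    if (size > best_size || (size == best_size && nb > best_bonds)) {
      best_map <<- mapA; best_size <<- size; best_bonds <<- nb
      best_pat <<- NULL
    } else if (size == best_size && nb == best_bonds && size >= min_size) {
      # deterministic tie-break: lexicographically smallest pattern
      gx <- induce_subgraph(molA, which(mapA > 0L))
      px <- pattern_string(gx, canonical_ranks(gx)$ranks)
      if (is.null(best_pat)) {
        gb <- induce_subgraph(molA, which(best_map > 0L))
        best_pat <<- pattern_string(gb, canonical_ranks(gb)$ranks)
      }
      if (px < best_pat) {
        best_map <<- mapA; best_size <<- size; best_bonds <<- nb
        best_pat <<- px
      }
    }
  }

  extend <- function(mapA, usedB, min_atom, excl) {
    nodes <<- nodes + 1L
    if (nodes %% 256L == 0L &&
        as.numeric(Sys.time() - t0, units = "secs") > timeout_s) {
      timed_out <<- TRUE
    }
    if (timed_out) return(invisible())
    consider(mapA)
    size <- sum(mapA > 0L)
    # bound: even mapping every remaining eligible atom cannot beat the best
    remaining <- sum(!excl & mapA == 0L & seq_len(nA) >= min_atom)
    if (size + min(remaining, nB - size) < best_size) return(invisible())
    mapped <- which(mapA > 0L)
    # frontier: eligible unmapped A atoms adjacent to the current mapping
    frontier <- setdiff(unique(unlist(adjA[mapped], use.names = FALSE)), mapped)
    frontier <- frontier[frontier >= min_atom & !excl[frontier]]
    if (length(frontier) == 0L) return(invisible())
    a <- frontier[1]
    candB <- which(compat[a, ] & !usedB)
    for (b in candB) {
      if (all(btA[a, mapped] == btB[b, mapA[mapped]])) {
        mapA[a] <- b; usedB[b] <- TRUE
        extend(mapA, usedB, min_atom, excl)
        mapA[a] <- 0L; usedB[b] <- FALSE
      }
    }
    # branch where atom `a` is excluded from this subgraph
    excl[a] <- TRUE
    extend(mapA, usedB, min_atom, excl)
    invisible()
  }

  for (a1 in seq_len(nA)) {
    if (timed_out) break
    if (nA - a1 + 1L <= best_size) break  # cannot contain a bigger subgraph
    for (b1 in which(compat[a1, ])) {
      mapA <- integer(nA); mapA[a1] <- b1
      usedB <- rep(FALSE, nB); usedB[b1] <- TRUE
      extend(mapA, usedB, a1 + 1L, rep(FALSE, nA))
      if (timed_out) break
    }
    compat[a1, ] <- FALSE  # subgraphs not containing a1 handled by later seeds
  }

  if (best_size < min_size) return(NULL)
  g <- induce_subgraph(molA, which(best_map > 0L))
  new_substructure(g, approximate = timed_out)
}

## ---- substructure monomorphism matching ----

# does pattern graph `p` occur in molecule `mol`? (subgraph monomorphism:
# every pattern bond must exist in the molecule with the same type; extra
# molecule bonds between mapped atoms are allowed)
match_pattern <- function(p, mol) {
  np <- p$n_atoms; nm <- mol$n_atoms
  if (np == 0L || np > nm) return(FALSE)
  btP <- matrix("", np, np)
  for (e in seq_along(p$bond_a)) {
    btP[p$bond_a[e], p$bond_b[e]] <- p$bond_type[e]
    btP[p$bond_b[e], p$bond_a[e]] <- p$bond_type[e]
  }
  btM <- bond_type_matrix(mol)
  symP <- atom_symbols(p); symM <- atom_symbols(mol)
  # order pattern atoms so each (after the first) touches an earlier one
  ord <- integer(0); left <- seq_len(np)
  ord <- 1L; left <- left[-1]
  while (length(left) > 0L) {
    nxt <- left[vapply(left, function(a) any(btP[a, ord] != ""), FALSE)]
    if (length(nxt) == 0L) { nxt <- left[1] }  # disconnected pattern
    ord <- c(ord, nxt[1]); left <- setdiff(left, nxt[1])
  }
  used <- rep(FALSE, nm)
  try_atom <- function(k, map) {
    if (k > np) return(TRUE)
    a <- ord[k]
    prior <- ord[seq_len(k - 1L)]
    for (b in which(symM == symP[a] & !used)) {
      ok <- TRUE
      for (j in seq_along(prior)) {
        t <- btP[a, prior[j]]
        if (nzchar(t) && btM[b, map[j]] != t) { ok <- FALSE; break }
      }
      if (ok) {
        used[b] <<- TRUE
        if (try_atom(k + 1L, c(map, b))) { used[b] <<- FALSE; return(TRUE) }
        used[b] <<- FALSE
      }
    }
    FALSE
  }
  try_atom(1L, integer(0))
}

## ---- vocabulary mining ----

# unrank the k-th unordered pair (1-based, row-major over i < j)
unrank_pair <- function(k, m) {
  i <- 1L
  while (k > m - i) { k <- k - (m - i); i <- i + 1L }
  c(i, i + k)
}

#' Mine a chemical-word vocabulary from a molecule corpus
#'
#' Samples `n_pairs` unordered molecule pairs uniformly without replacement
#' (seeded), computes the MCS of each, and aggregates identical patterns (by
#' canonical certificate) into a frequency-ranked vocabulary.
#'
#' @param molecules list of `molgraph` objects or character vector of SMILES.
#' @param n_pairs number of pairs to sample; capped (with a warning) at the
#'   number of distinct pairs.
#' @param seed integer seed for pair sampling.
#' @param min_size minimum substructure size (atoms).
#' @param timeout_s per-pair MCS time budget.
#' @return a `cld_vocabulary`: data.frame with `pattern`, `frequency`,
#'   `atom_count`, `bond_count`, frequencies non-increasing; pattern graphs
#'   and the sampling metadata are carried as attributes.
#' @export
mine_clds <- function(molecules, n_pairs, seed, min_size = 3L, timeout_s = 10) {
  if (is.character(molecules)) molecules <- parse_molecules(molecules)
  bad <- vapply(molecules, is.null, FALSE)
  if (any(bad)) stop(sum(bad), " molecule(s) failed to parse")
  m <- length(molecules)
  if (m < 2L) stop("need at least 2 molecules")
  stopifnot(n_pairs >= 1L)
  total <- m * (m - 1) / 2
  if (n_pairs > total) {
    warning("n_pairs (", n_pairs, ") exceeds the number of distinct pairs (",
            total, "); capped")
    n_pairs <- total
  }
  picks <- with_seed(seed, sample.int(total, n_pairs))
  counts <- new.env(parent = emptyenv())
  for (k in picks) {
    ij <- unrank_pair(k, m)
    s <- mcs(molecules[[ij[1]]], molecules[[ij[2]]],
             min_size = min_size, timeout_s = timeout_s)
    if (is.null(s)) next
    prev <- counts[[s$certificate]]
    if (is.null(prev)) {
      counts[[s$certificate]] <- list(sub = s, freq = 1L)
    } else {
      prev$freq <- prev$freq + 1L
      counts[[s$certificate]] <- prev
    }
  }
  entries <- mget(ls(counts), envir = counts)
  if (length(entries) == 0L) {
    vocab <- data.frame(pattern = character(0), frequency = integer(0),
                        atom_count = integer(0), bond_count = integer(0))
    graphs <- list()
  } else {
    vocab <- data.frame(
      pattern = vapply(entries, function(e) e$sub$pattern, ""),
      frequency = vapply(entries, function(e) e$freq, 1L),
      atom_count = vapply(entries, function(e) e$sub$atom_count, 1L),
      bond_count = vapply(entries, function(e) e$sub$bond_count, 1L),
      stringsAsFactors = FALSE
    )
    ord <- order(-vocab$frequency, -vocab$atom_count, vocab$pattern)
    vocab <- vocab[ord, , drop = FALSE]
    rownames(vocab) <- NULL
    graphs <- lapply(entries, function(e) e$sub$graph)[ord]
  }
  structure(vocab, graphs = graphs, n_pairs = n_pairs, seed = seed,
            min_size = min_size, class = c("cld_vocabulary", "data.frame"))
}

#' @export
print.cld_vocabulary <- function(x, ...) {
  cat("<cld_vocabulary> ", nrow(x), " patterns from ", attr(x, "n_pairs"),
      " sampled pairs (seed ", attr(x, "seed"), ")\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Binary CLD feature vector for one reaction
#'
#' Bit k is 1 iff the k-th ranked vocabulary substructure occurs (subgraph
#' match) in ANY reactant or product molecule of the reaction.
#'
#' @param reaction reaction SMILES string or a list with `reactants` /
#'   `products` SMILES vectors.
#' @param vocab a [mine_clds()] vocabulary.
#' @param K number of top-ranked patterns to use; must not exceed the
#'   vocabulary size.
#' @return integer 0/1 vector of length `K` named by pattern.
#' @export
cld_features <- function(reaction, vocab, K = nrow(vocab)) {
  stopifnot(inherits(vocab, "cld_vocabulary"))
  if (K > nrow(vocab)) stop("K (", K, ") exceeds vocabulary size (", nrow(vocab), ")")
  sides <- if (is.character(reaction)) split_rsmi(reaction) else reaction
  smis <- unique(c(sides$reactants, sides$products))
  mols <- parse_molecules(smis)
  if (any(vapply(mols, is.null, FALSE))) stop("unparseable molecule in reaction")
  graphs <- attr(vocab, "graphs")[seq_len(K)]
  bits <- vapply(graphs, function(p) {
    any(vapply(mols, function(m) match_pattern(p, m), FALSE))
  }, FALSE)
  stats::setNames(as.integer(bits), vocab$pattern[seq_len(K)])
}

#' CLD feature matrix for a record set
#'
#' @param records clean record data.frame with an `rsmi` column.
#' @inheritParams cld_features
#' @return integer matrix `nrow(records) x K`, family attribute "cld".
#' @export
cld_matrix <- function(records, vocab, K = nrow(vocab)) {
  stopifnot(is.data.frame(records))
  if (K > nrow(vocab)) stop("K (", K, ") exceeds vocabulary size (", nrow(vocab), ")")
  graphs <- attr(vocab, "graphs")[seq_len(K)]
  # per-unique-molecule match cache: reactions share substrates
  sides <- lapply(records$rsmi, split_rsmi)
  mol_sets <- lapply(sides, function(s) unique(c(s$reactants, s$products)))
  uniq <- unique(unlist(mol_sets, use.names = FALSE))
  mols <- parse_molecules(uniq)
  hit <- matrix(FALSE, length(uniq), K)
  for (u in seq_along(uniq)) {
    if (is.null(mols[[u]])) next
    hit[u, ] <- vapply(graphs, function(p) match_pattern(p, mols[[u]]), FALSE)
  }
  X <- matrix(0L, nrow(records), K)
  for (i in seq_len(nrow(records))) {
    rows <- match(mol_sets[[i]], uniq)
    X[i, ] <- as.integer(apply(hit[rows, , drop = FALSE], 2, any))
  }
  colnames(X) <- paste0("cld_", seq_len(K))
  rownames(X) <- records$reaction_id
  attr(X, "family") <- rep("cld", K)
  X
}

#' Write / read a CLD vocabulary as two-column TSV
#'
#' @param vocab a `cld_vocabulary`.
#' @param path TSV path (pattern, frequency).
#' @return invisibly the path; `read_cld_vocabulary()` returns the rebuilt
#'   vocabulary (pattern graphs re-parsed from the pattern strings).
#' @export
write_cld_vocabulary <- function(vocab, path) {
  utils::write.table(vocab[, c("pattern", "frequency")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cld_vocabulary
#' @export
read_cld_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  graphs <- lapply(df$pattern, parse_pattern)
  df$atom_count <- vapply(graphs, function(g) g$n_atoms, 1L)
  df$bond_count <- vapply(graphs, function(g) length(g$bond_a), 1L)
  ord <- order(-df$frequency, -df$atom_count, df$pattern)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, graphs = graphs[ord], n_pairs = NA_integer_, seed = NA_integer_,
            class = c("cld_vocabulary", "data.frame"))
}
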
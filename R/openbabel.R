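# Molecule ingestion via the OpenBabel CLI.
#
# All SMILES entering the package pass through `obabel`, run in batch with
# `-e` (continue past invalid records). Each input line carries a synthetic
# title m<i>; titles missing from the output identify the records OpenBabel
# rejected, so one bad SMILES never poisons a batch. Parsed molecules are
# memoized per session keyed on the raw SMILES string.

.mol_cache <- new.env(parent = emptyenv())

ob_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH")
  p
}

# Run obabel over a character vector of input lines; returns stdout lines.
ob_run <- function(lines, in_fmt, out_fmt, args = character()) {
  fin <- tempfile(fileext = paste0(".", in_fmt))
  fout <- tempfile(fileext = paste0(".", out_fmt))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(lines, fin)
  suppressWarnings(system2(
    ob_path(),
    c(paste0("-i", in_fmt), fin, paste0("-o", out_fmt), "-O", fout, "-e", args),
    stdout = FALSE, stderr = FALSE
  ))
  if (!file.exists(fout)) character(0) else readLines(fout, warn = FALSE)
}

bond_type_map <- c("1" = "1", "2" = "2", "3" = "3", "ar" = "ar",
                   "am" = "1", "du" = "1", "un" = "1", "nc" = "1")

# Parse a whole multi-molecule MOL2 file in a few vectorized passes; one
# regex sweep per needed column instead of per-line splitting.
parse_mol2_batch <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0L) return(list())
  titles <- trimws(lines[starts + 1L])
  counts <- strsplit(trimws(lines[starts + 2L]), "\\s+")
  n_atoms <- vapply(counts, function(x) as.integer(x[1]), 1L)
  n_bonds <- vapply(counts, function(x) as.integer(x[2]), 1L)
  # assign each section head to its molecule block (0-bond molecules may
  # lack a BOND section, so heads cannot be paired positionally)
  at_heads0 <- grep("^@<TRIPOS>ATOM", lines)
  bd_heads0 <- grep("^@<TRIPOS>BOND", lines)
  at_heads <- rep(NA_integer_, length(starts))
  at_heads[findInterval(at_heads0, starts)] <- at_heads0
  bd_heads <- rep(NA_integer_, length(starts))
  bd_heads[findInterval(bd_heads0, starts)] <- bd_heads0
  n_atoms[is.na(at_heads)] <- 0L
  n_bonds[is.na(bd_heads)] <- 0L
  atom_rows <- unlist(mapply(function(h, k) if (!is.na(h) && k > 0) (h + 1L):(h + k) else integer(0),
                             at_heads, n_atoms, SIMPLIFY = FALSE))
  bond_rows <- unlist(mapply(function(h, k) if (!is.na(h) && k > 0) (h + 1L):(h + k) else integer(0),
                             bd_heads, n_bonds, SIMPLIFY = FALSE))
  atom_type <- sub("^\\s*\\S+\\s+\\S+\\s+\\S+\\s+\\S+\\s+\\S+\\s+(\\S+).*$",
                   "\\1", lines[atom_rows])
  bl <- lines[bond_rows]
  b_a <- as.integer(sub("^\\s*\\S+\\s+(\\S+).*$", "\\1", bl))
  b_b <- as.integer(sub("^\\s*\\S+\\s+\\S+\\s+(\\S+).*$", "\\1", bl))
  b_t <- sub("^\\s*\\S+\\s+\\S+\\s+\\S+\\s+(\\S+).*$", "\\1", bl)
  b_t <- unname(bond_type_map[b_t])
  b_t[is.na(b_t)] <- "1"
  a_off <- c(0L, cumsum(n_atoms))
  b_off <- c(0L, cumsum(n_bonds))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    na <- n_atoms[i]; nb <- n_bonds[i]
    if (is.na(na) || na < 1L) next
    element <- sub("\\..*$", "", atom_type[(a_off[i] + 1L):(a_off[i] + na)])
    if (nb > 0L) {
      sel <- (b_off[i] + 1L):(b_off[i] + nb)
      bond_a <- b_a[sel]; bond_b <- b_b[sel]; bond_type <- b_t[sel]
    } else {
      bond_a <- integer(0); bond_b <- integer(0); bond_type <- character(0)
    }
    aromatic <- rep(FALSE, na)
    ar <- bond_type == "ar"
    aromatic[unique(c(bond_a[ar], bond_b[ar]))] <- TRUE
    out[[i]] <- list(title = titles[i], n_atoms = na, element = element,
                     aromatic = aromatic, bond_a = bond_a, bond_b = bond_b,
                     bond_type = bond_type)
  }
  out[!vapply(out, is.null, FALSE)]
}

#' Parse SMILES strings into molecular graphs
#'
#' Converts SMILES to heavy-atom molecular graphs (element, aromaticity from
#' perceived aromatic bonds, bond orders) via OpenBabel, together with the
#' canonical SMILES used for deduplication keys. Invalid SMILES yield `NULL`
#' entries rather than an error, mirroring the prune-don't-crash handling of
#' literature reaction sets.
#'
#' @param smiles character vector of SMILES strings.
#' @param cache reuse (and extend) the per-session molecule cache.
#' @return a list parallel to `smiles`; each element is a `molgraph` (see
#'   [molgraph()]) or `NULL` for unparseable input.
#' @export
parse_molecules <- function(smiles, cache = TRUE) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  if (length(smiles) == 0L) return(out)
  key <- smiles
  todo <- unique(key[!vapply(key, function(k) cache && exists(k, envir = .mol_cache), FALSE)])
  # whitespace inside a SMILES would corrupt the title mapping; reject early
  bad_ws <- grepl("\\s", todo)
  for (k in todo[bad_ws]) assign(k, list(NULL), envir = .mol_cache)
  todo <- todo[!bad_ws]
  if (length(todo) > 0L) {
    titles <- paste0("m", seq_along(todo))
    inlines <- paste(todo, titles)
    mol2 <- ob_run(inlines, "smi", "mol2")
    can <- ob_run(inlines, "smi", "can")
    canmap <- character(0)
    if (length(can) > 0L) {
      parts <- strsplit(can, "\t", fixed = TRUE)
      ok <- lengths(parts) >= 2L
      canmap <- stats::setNames(
        vapply(parts[ok], `[[`, "", 1L),
        trimws(vapply(parts[ok], `[[`, "", 2L))
      )
    }
    blocks <- parse_mol2_batch(mol2)
    parsed <- stats::setNames(blocks, vapply(blocks, `[[`, "", "title"))
    for (i in seq_along(todo)) {
      g <- parsed[[titles[i]]]
      if (is.null(g)) {
        assign(todo[i], list(NULL), envir = .mol_cache)
      } else {
        m <- new_molgraph(g, smiles = todo[i],
                          cansmi = unname(canmap[titles[i]]) %||% NA_character_)
        assign(todo[i], list(m), envir = .mol_cache)
      }
    }
  }
  for (i in seq_along(key)) {
    out[i] <- get(key[i], envir = .mol_cache)  # keeps NULL entries in place
  }
  if (!cache) for (k in todo) if (exists(k, envir = .mol_cache)) rm(list = k, envir = .mol_cache)
  out
}

#' Clear the per-session molecule cache
#' @return invisibly, the number of entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(envir = .mol_cache))
  rm(list = ls(envir = .mol_cache), envir = .mol_cache)
  invisible(n)
}

# Batch physicochemical properties through obabel --append.
# Returns a data.frame with one row per input SMILES (NA rows on failure).
ob_properties <- function(smiles,
                          props = c("MW", "logP", "TPSA", "MR", "HBD", "HBA1")) {
  n <- length(smiles)
  res <- matrix(NA_real_, n, length(props), dimnames = list(NULL, props))
  if (n == 0L) return(as.data.frame(res))
  uniq <- unique(smiles)
  titles <- paste0("m", seq_along(uniq))
  out <- ob_run(paste(uniq, titles), "smi", "smi",
                c("--append", paste(props, collapse = " ")))
  vals <- matrix(NA_real_, length(uniq), length(props))
  if (length(out) > 0L) {
    for (line in out) {
      fields <- strsplit(strsplit(line, "\t", fixed = TRUE)[[1]][2], "\\s+")[[1]]
      idx <- match(fields[1], titles)
      if (!is.na(idx) && length(fields) == length(props) + 1L) {
        vals[idx, ] <- suppressWarnings(as.numeric(fields[-1]))
      }
    }
  }
  res[] <- vals[match(smiles, uniq), , drop = FALSE]
  as.data.frame(res)
}
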
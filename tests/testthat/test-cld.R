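test_that("mcs handles the canonical textbook cases", {
  s <- mcs("c1ccccc1", "c1ccccc1")
  expect_equal(s$atom_count, 6)
  expect_equal(s$bond_count, 6)

  expect_null(mcs("C", "N"))  # nothing of size >= 3 in common

  ring <- mcs("Cc1ccccc1", "Oc1ccccc1")
  expect_equal(ring$atom_count, 6)
  expect_true(all(rxnaudit:::parse_pattern(ring$pattern)$aromatic))

  # aromatic and aliphatic six-rings never match
  expect_null(mcs("c1ccccc1", "C1CCCCC1"))
})

test_that("mcs is symmetric, self-complete and size-bounded", {
  pairs <- list(c("CC(F)CO", "CC(F)CN"), c("CCOC(=O)C", "CCNC(=O)C"),
                c("Cc1ccccc1", "CCc1ccncc1"), c("C1CCCCC1", "C1CCCC1"))
  for (p in pairs) {
    a <- mcs(p[1], p[2]); b <- mcs(p[2], p[1])
    expect_equal(a$pattern, b$pattern, info = paste(p, collapse = " vs "))
    expect_lte(a$atom_count, min(molgraph(p[1])$n_atoms, molgraph(p[2])$n_atoms))
  }
  for (smi in c("CCO", "Cc1ccccc1", "CC(=O)OCC", "C1CCNCC1")) {
    self <- mcs(smi, smi)
    expect_equal(self$atom_count, molgraph(smi)$n_atoms, info = smi)
  }
})

test_that("mcs size equals the exhaustive subgraph-enumeration oracle", {
  smis <- c("CCO", "CC=O", "CC(=O)O", "CCN", "CC(C)C", "c1ccoc1",
            "C1CCCC1", "CC#N", "OCCO", "CC(F)C")
  mols <- lapply(smis, molgraph)
  for (i in seq_along(mols)) for (j in i:length(mols)) {
    want <- brute_mcs_size(mols[[i]], mols[[j]])
    got <- mcs(mols[[i]], mols[[j]], min_size = 1)
    expect_equal(if (is.null(got)) 0L else got$atom_count, want,
                 info = paste(smis[i], "vs", smis[j]))
  }
})

test_that("pattern strings survive a write/parse round trip", {
  for (smi in c("Cc1ccccc1", "CC(=O)OCC", "C1CCNCC1", "c1ccc2ccccc2c1")) {
    m <- molgraph(smi)
    s <- mcs(m, m)
    g <- rxnaudit:::parse_pattern(s$pattern)
    expect_equal(g$n_atoms, s$atom_count, info = smi)
    expect_equal(length(g$bond_a), s$bond_count, info = smi)
    # re-canonicalizing the parsed graph reproduces the same string
    cr <- rxnaudit:::canonical_ranks(g)
    expect_equal(rxnaudit:::pattern_string(g, cr$ranks), s$pattern, info = smi)
  }
})

test_that("the matcher agrees with OpenBabel SMARTS search on mined patterns", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  targets <- c("CCO", "CC(=O)OCC", "Cc1ccccc1", "Oc1ccncc1", "CC(F)CC",
               "c1ccc2ccccc2c1", "C1CCCCC1", "CCOC(=O)c1ccccc1")
  sdf <- ChemmineR::smiles2sdf(setNames(targets, paste0("t", seq_along(targets))))
  mols <- parse_molecules(targets)
  patterns <- c("C-C-O", "C-C(=O)-O", "c:1:c:c:c:c:c:1", "C-C(-C)-F")
  for (p in patterns) {
    ours <- vapply(mols, function(m) {
      rxnaudit:::match_pattern(rxnaudit:::parse_pattern(p), m)
    }, FALSE)
    ob <- ChemmineR::smartsSearchOB(sdf, p) > 0
    expect_equal(unname(ours), unname(ob), info = p)
  }
})

test_that("vocabulary mining is seeded, ranked, and capped", {
  mols <- c("Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "CCc1ccccc1", "CCO",
            "CCCO", "CCN", "CCCN")
  v1 <- mine_clds(mols, n_pairs = 28, seed = 42)  # every distinct pair
  v2 <- mine_clds(mols, n_pairs = 28, seed = 42)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_true(all(diff(v1$frequency) <= 0))
  expect_true(all(v1$frequency >= 1))
  expect_true(all(v1$atom_count >= 3))
  # the four aryl molecules make the benzene ring the most popular word
  expect_equal(v1$pattern[1], "c:1:c:c:c:c:c:1")

  expect_warning(v3 <- mine_clds(c("CCO", "CCN"), n_pairs = 5, seed = 1),
                 "capped")
  # two identical molecules: the vocabulary is that molecule's own pattern
  v4 <- mine_clds(c("CCO", "CCO"), n_pairs = 1, seed = 1)
  expect_equal(nrow(v4), 1)
  expect_equal(v4$frequency, 1L)
  expect_equal(v4$atom_count, 3L)
})

test_that("cld feature bits fire on any reaction molecule, zero otherwise", {
  mols <- c("Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "CCc1ccccc1")
  vocab <- mine_clds(mols, n_pairs = 6, seed = 7)
  ring_bit <- which(vocab$pattern == "c:1:c:c:c:c:c:1")[1]

  f <- cld_features("Cc1ccccc1>>Oc1ccccc1", vocab)
  expect_equal(unname(f[ring_bit]), 1L)
  # fully acyclic reaction vs an all-ring vocabulary: all-zero vector
  f0 <- cld_features("CCO>>CC=O", vocab, K = ring_bit)
  expect_true(all(f0 == 0L))
  # an inert aromatic spectator reactant flips the ring bit on
  fsp <- cld_features("CCO.Cc1ccccc1>>CC=O.Cc1ccccc1", vocab)
  expect_equal(unname(fsp[ring_bit]), 1L)

  expect_error(cld_features("CCO>>CC=O", vocab, K = nrow(vocab) + 1), "exceeds")
})

test_that("vocabularies round-trip through the TSV interface", {
  mols <- c("Cc1ccccc1", "Oc1ccccc1", "CCO", "CCCO", "CCOC(=O)C", "CCN")
  vocab <- mine_clds(mols, n_pairs = 10, seed = 3)
  path <- file.path(tempdir(), "vocab.tsv")
  write_cld_vocabulary(vocab, path)
  back <- read_cld_vocabulary(path)
  expect_equal(back$pattern, vocab$pattern)
  expect_equal(back$frequency, vocab$frequency)
  expect_equal(back$atom_count, vocab$atom_count)
  # the reloaded vocabulary drives identical features
  recs <- data.frame(reaction_id = "r1", rsmi = "CCO.Cc1ccccc1>>CCOC(=O)C",
                     yield_pct = 50, time_h = 1, solvent = NA, temperature_c = NA)
  expect_identical(cld_matrix(recs, vocab), cld_matrix(recs, back))
})

test_that("mined word frequencies fall off like a rank power law", {
  gen <- planted_reactions(40, label_noise = 0, seed = 13)
  smis <- unique(unlist(lapply(gen$records$rsmi, function(r) {
    s <- rxnaudit:::split_rsmi(r); c(s$reactants, s$products)
  })))
  vocab <- mine_clds(smis, n_pairs = 120, seed = 5, timeout_s = 2)
  expect_gt(nrow(vocab), 5)
  keep <- vocab$frequency >= 1
  lr <- log(seq_len(sum(keep))); lf <- log(vocab$frequency[keep])
  # strong negative rank correlation of log-frequency vs log-rank
  expect_lt(cor(lr, lf, method = "spearman"), -0.7)
})
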
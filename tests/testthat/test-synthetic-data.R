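test_that("generators are pure functions of their spec", {
  g1 <- gaussian_dataset(200, d = 3, delta = 1.5, seed = 41)
  g2 <- gaussian_dataset(200, d = 3, delta = 1.5, seed = 41)
  expect_identical(g1, g2)
  p1 <- planted_features(100, seed = 42)
  p2 <- planted_features(100, seed = 42)
  expect_identical(p1, p2)
  r1 <- planted_reactions(40, duplicate_rate = 0.2, missing_rate = 0.2, seed = 43)
  r2 <- planted_reactions(40, duplicate_rate = 0.2, missing_rate = 0.2, seed = 43)
  expect_identical(r1, r2)
  m1 <- messy_records(30, seed = 44)
  m2 <- messy_records(30, seed = 44)
  expect_identical(m1$records, m2$records)
  # and a written file is byte-identical under the same seed
  f1 <- file.path(tempdir(), "m1.csv"); f2 <- file.path(tempdir(), "m2.csv")
  messy_records(30, seed = 44, path = f1)
  messy_records(30, seed = 44, path = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gaussian datasets carry the closed-form Bayes error", {
  expect_equal(gaussian_dataset(10, delta = 0, seed = 1)$bayes_error, 0.5)
  expect_equal(gaussian_dataset(10, delta = 2, seed = 1)$bayes_error,
               pnorm(-1))
  expect_equal(gaussian_dataset(10, delta = 10, seed = 1)$bayes_error,
               pnorm(-5))
  expect_true(is.na(gaussian_dataset(10, priors = c(0.3, 0.7), seed = 1)$bayes_error))
  expect_error(gaussian_dataset(10, priors = c(0.6, 0.6)), "priors")
  # empirical class means land where the generator parameters say
  g <- gaussian_dataset(4000, d = 2, delta = 3, seed = 2)
  expect_equal(mean(g$X[g$y == 1, 1]) - mean(g$X[g$y == 0, 1]), 3,
               tolerance = 0.1)
})

test_that("planted feature labels follow the deterministic rule plus flips", {
  pf <- planted_features(500, n_informative = 5, n_noise = 5,
                         label_noise = 0.25, seed = 45)
  score <- rowSums(pf$X[, pf$informative])
  expect_equal(pf$truth$clean_labels, as.integer(score > 0))
  expect_equal(pf$y != pf$truth$clean_labels, pf$truth$flipped)
  expect_lt(abs(mean(pf$truth$flipped) - 0.25), 3 * sqrt(0.25 * 0.75 / 500))
  expect_equal(pf$bayes_error, 0.25)
})

test_that("planted reactions satisfy the generator contract", {
  pr <- planted_reactions(150, label_noise = 0.1, duplicate_rate = 0.15,
                          missing_rate = 0.1, seed = 46)
  recs <- pr$records
  base <- recs[seq_len(150), ]
  expect_true(all(base$yield_pct >= 0 & base$yield_pct <= 100))
  expect_true(all(base$time_h > 0, na.rm = TRUE))
  # every reaction SMILES parses
  cl <- clean_reactions(recs)
  expect_equal(nrow(cl$rejects), 0)
  # base reactions are key-distinct; duplicates collapse back to the base
  expect_equal(length(unique(cl$records$dedup_key)), 150)
  dd <- deduplicate_reactions(cl$records, "yield")
  expect_equal(nrow(dd), 150)
  expect_equal(nrow(recs) - 150, pr$truth$n_duplicates)
  # thresholding the back-generated yields reproduces the noisy labels
  lab <- label_reactions(dd, label_spec("yield", threshold = 65))
  idx <- match(lab$records$dedup_key, cl$records$dedup_key[seq_len(150)])
  expect_equal(lab$labels, pr$truth$noisy_labels[idx])
  # flips happen at roughly the stated rate
  expect_lt(abs(mean(pr$truth$flipped) - 0.1), 3 * sqrt(0.1 * 0.9 / 150))
})

test_that("duplicate injection removes the expected count at dedup", {
  pr <- planted_reactions(400, label_noise = 0, duplicate_rate = 0.1, seed = 47)
  n_dups <- pr$truth$n_duplicates
  # binomial draw around 40
  expect_gt(n_dups, 20); expect_lt(n_dups, 60)
  dd <- deduplicate_reactions(clean_reactions(pr$records)$records, "yield")
  expect_equal(nrow(pr$records) - nrow(dd), n_dups)
})

test_that("correlation ranking recovers the planted reaction features", {
  pr <- planted_reactions(3000, label_noise = 0.1, seed = 48)
  cl <- clean_reactions(pr$records)
  lab <- label_reactions(deduplicate_reactions(cl$records, "yield"),
                         label_spec("yield"))
  X <- reaction_features(lab$records)
  rk <- correlation_rank(X, lab$labels)
  inf <- pr$truth$informative_features
  top <- rk$feature[seq_len(2 * length(inf))]
  expect_gte(mean(inf %in% top), 0.9)
})

test_that("messy record manifests predict the cleaning pipeline exactly", {
  mm <- messy_records(60, seed = 49)
  cl <- clean_reactions(mm$records)
  man <- mm$manifest
  for (reason in names(man$rejects)) {
    expect_equal(sum(cl$rejects$reason == reason), man$rejects[[reason]],
                 info = reason)
  }
  expect_equal(nrow(cl$records), man$n_clean)
  dd <- deduplicate_reactions(cl$records, "yield")
  expect_equal(nrow(dd), man$n_after_dedup)
  # survivors carry the max yield / min time stated in the manifest
  expect_equal(dd$yield_pct[match(names(man$survivor_yield), dd$rsmi)],
               unname(unlist(man$survivor_yield)))
  dt <- deduplicate_reactions(cl$records, "time")
  expect_equal(dt$time_h[match(names(man$survivor_time), dt$rsmi)],
               unname(unlist(man$survivor_time)))
  # all-valid input: every record survives
  m2 <- messy_records(8, seed = 50)
  keep <- m2$manifest$categories %in% c("valid", "duplicate")
  cl2 <- clean_reactions(m2$records[keep, ])
  expect_equal(nrow(cl2$records), sum(keep))
})
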
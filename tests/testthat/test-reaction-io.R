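test_that("reaction SMILES parse into reactant/agent/product molecule lists", {
  r <- parse_rsmi("CCO>>CC=O")
  expect_length(r$reactants, 1)
  expect_length(r$agents, 0)
  expect_length(r$products, 1)
  expect_equal(r$reactants[[1]]$cansmi, "CCO")

  r2 <- parse_rsmi("CC(=O)O.CCO>[H+]>CC(=O)OCC.O")
  expect_length(r2$reactants, 2)
  expect_length(r2$agents, 1)
  expect_length(r2$products, 2)

  expect_error(parse_rsmi("CCO>CC=O"), "two '>'")
  expect_error(parse_rsmi(">>CCO"), "at least one reactant")
  expect_error(parse_rsmi("XX)(>>CCO"), "unparseable")
})

test_that("cleaning prunes each failure mode with its reason code", {
  raw <- data.frame(
    reaction_id = paste0("r", 1:6),
    rsmi = c("CCO>>CC=O", "CCO>CC=O", "XX)(>>C", "CCO>>CC=O",
             "CCO>>CC=O", "CCO>>CC=O"),
    yield_pct = c(80, 50, 50, NA, 150, 60),
    time_h = c(2, 2, 2, NA, 2, -1),
    solvent = NA_character_, temperature_c = NA_real_,
    stringsAsFactors = FALSE
  )
  cl <- clean_reactions(raw)
  expect_equal(nrow(cl$records), 1)
  expect_setequal(cl$rejects$reason,
                  c("malformed_rsmi", "unparseable_smiles", "missing_outcomes",
                    "yield_out_of_range", "nonpositive_time"))
  expect_equal(cl$records$reaction_id, "r1")
})

test_that("deduplication keeps highest yield / shortest time per reaction", {
  recs <- data.frame(
    reaction_id = c("a", "b", "c"),
    rsmi = c("CCO>>CC=O", "OCC>[H+]>CC=O", "CCO>>CCC=O"),
    yield_pct = c(40, 80, 70), time_h = c(24, 2, 5),
    solvent = NA_character_, temperature_c = NA_real_,
    stringsAsFactors = FALSE
  )
  # a and b are the same reaction (spelling + agent differences); c is not
  same <- c("CCO>>CC=O", "OCC>[H+]>CC=O")
  dy <- deduplicate_reactions(recs, "yield")
  expect_equal(nrow(dy), 2)
  expect_equal(dy$yield_pct[dy$rsmi %in% same], 80)
  dt <- deduplicate_reactions(recs, "time")
  expect_equal(dt$time_h[dt$rsmi %in% same], 2)
  # records with distinct product sets are both retained
  expect_true(any(grepl("CCC=O", dy$rsmi)))
})

test_that("deduplication is idempotent and never increases survivors' rank", {
  gen <- planted_reactions(60, label_noise = 0, duplicate_rate = 0.4, seed = 3)
  cl <- clean_reactions(gen$records)
  d1 <- deduplicate_reactions(cl$records, "yield")
  d2 <- deduplicate_reactions(d1, "yield")
  expect_identical(d1, d2)
  expect_lte(nrow(d1), nrow(cl$records))
  expect_setequal(unique(cl$records$dedup_key), d1$dedup_key)
  # every survivor carries the max yield within its key group
  grp <- split(cl$records$yield_pct, cl$records$dedup_key)
  expect_equal(d1$yield_pct[order(d1$dedup_key)],
               unname(vapply(grp[sort(names(grp))], max, 0)))
})

test_that("median threshold uses the lower-middle convention", {
  mk <- function(y) data.frame(yield_pct = y, time_h = NA_real_)
  expect_equal(median_threshold(mk(c(10, 65, 90)), "yield"), 65)
  expect_equal(median_threshold(mk(c(10, 60, 70, 90)), "yield"), 60)
  expect_equal(median_threshold(mk(50), "yield"), 50)
  # cross-check against a sort-and-index oracle on random draws
  for (s in 1:5) {
    set.seed(s)
    v <- sample(1:100, sample(3:20, 1))
    expect_equal(median_threshold(mk(v), "yield"),
                 sort(v)[ceiling(length(v) / 2)])
  }
  expect_error(median_threshold(mk(NA_real_), "yield"), "no observed")
})

test_that("labeling is strict-above with ties to class 0 and partitions the set", {
  recs <- data.frame(
    reaction_id = paste0("r", 1:4),
    rsmi = "CCO>>CC=O",
    yield_pct = c(90, 65, 10, NA), time_h = c(1, 12, 48, 2),
    solvent = NA_character_, temperature_c = NA_real_,
    stringsAsFactors = FALSE
  )
  lab <- label_reactions(recs, label_spec("yield", threshold = 65))
  expect_equal(lab$labels, c(1L, 0L, 0L))
  expect_equal(lab$n_excluded, 1L)
  expect_equal(nrow(lab$records) + lab$n_excluded, nrow(recs))

  # for time the positive class is SLOW (value > threshold)
  labt <- label_reactions(recs, label_spec("time", threshold = 12))
  expect_equal(labt$labels, c(0L, 0L, 1L, 0L))
  expect_equal(label_spec("time")$positive_class_name, "slow")

  expect_error(label_reactions(recs[0, ], label_spec("yield")), "no labelable")
  expect_error(label_reactions(recs, label_spec("yield", threshold = 95)),
               "strictly inside")
})

test_that("reaction tables round-trip through CSV and rsmi files", {
  gen <- planted_reactions(20, label_noise = 0, seed = 5)
  csv <- file.path(tempdir(), "reactions.csv")
  write.csv(setNames(gen$records,
                     c("id", "rsmi", "yield", "time", "solvent", "temperature")),
            csv, row.names = FALSE)
  rt <- read_reactions(csv)
  expect_equal(rt$rsmi, gen$records$rsmi)
  expect_equal(rt$yield_pct, gen$records$yield_pct)
  expect_equal(rt$reaction_id, gen$records$reaction_id)

  rsmif <- file.path(tempdir(), "reactions.rsmi")
  writeLines(gen$records$rsmi, rsmif)
  rr <- read_reactions(rsmif)
  expect_equal(rr$rsmi, gen$records$rsmi)
  expect_true(all(is.na(rr$yield_pct)))

  lab <- label_reactions(clean_reactions(rt)$records, label_spec("yield"))
  out <- file.path(tempdir(), "labeled.csv")
  write_labeled_csv(lab, out)
  back <- read.csv(out)
  expect_equal(back$label, lab$labels)
})
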
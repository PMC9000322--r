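test_that("standardization canonicalizes, strips salts and is idempotent", {
  m <- standardize("C1=CC=CC=C1")[[1]]
  b <- standardize("c1ccccc1")[[1]]
  expect_identical(m$smiles, b$smiles)   # kekulized and aromatic inputs agree

  # idempotence
  again <- standardize(m$smiles)[[1]]
  expect_identical(again$smiles, m$smiles)

  # salts/solvents reduced to the largest organic component (ethanol: 3 heavy atoms)
  salt <- standardize("CCO.[Na+].[Cl-]")[[1]]
  expect_equal(nrow(salt$atoms), 3L)
  expect_identical(salt$smiles, standardize("CCO")[[1]]$smiles)

  # carboxylate neutralized
  ac <- standardize("CC(=O)[O-]")[[1]]
  expect_identical(ac$smiles, standardize("CC(=O)O")[[1]]$smiles)

  expect_error(standardize("not_a_smiles(("), "unparseable")
})

test_that("canonicalization is idempotent across the fixture collection", {
  smi <- unname(vapply(full_mols(), `[[`, "", "smiles"))
  expect_identical(csfpr:::ob_canonical(smi), smi)
})

test_that("molecule files round-trip through .smi and .tsv", {
  mols <- ref_mols()
  smi <- tempfile(fileext = ".smi")
  tsv <- tempfile(fileext = ".tsv")
  write_molecules(mols, smi)
  write_molecules(mols, tsv)
  back1 <- read_molecules(smi)
  back2 <- read_molecules(tsv)
  expect_identical(vapply(back1, `[[`, "", "smiles"),
                   vapply(mols, `[[`, "", "smiles"))
  expect_identical(vapply(back2, `[[`, "", "id"),
                   vapply(mols, `[[`, "", "id"))
})

test_that("activity-record curation applies every filter", {
  tab <- generate_fixture_activity_table(n_clean = 10, seed = 1)
  cur <- curate_activity_records(tab)
  expect_equal(nrow(cur), 10L)
  expect_true(all(startsWith(cur$compound_id, "OK")))

  # each dirty row fails exactly one filter
  dirty <- tab[!startsWith(tab$compound_id, "OK"), ]
  for (i in seq_len(nrow(dirty)))
    expect_equal(nrow(curate_activity_records(dirty[i, , drop = FALSE])), 0L)

  # output is a subset of input and curation is idempotent
  expect_true(all(cur$compound_id %in% tab$compound_id))
  expect_identical(curate_activity_records(cur), cur)
})

test_that("relation and flag filters match the protocol wording", {
  tab <- generate_fixture_activity_table(n_clean = 2, seed = 2)
  gt <- tab[1, ]; gt$standard_relation <- ">"
  expect_equal(nrow(curate_activity_records(gt)), 0L)
  fl <- tab[1, ]; fl$flags <- "inconclusive"
  expect_equal(nrow(curate_activity_records(fl)), 0L)
  # 6 records of which exactly 2 survive
  six <- rbind(tab[1:2, ], gt, fl,
               transform(tab[1, ], compound_id = "X1", confidence_score = 5L),
               transform(tab[2, ], compound_id = "X2", standard_value_nM = 99999))
  expect_equal(nrow(curate_activity_records(six)), 2L)
})

test_that("curation hooks remove anti-targets and flagged interference", {
  tab <- generate_fixture_activity_table(n_clean = 4, seed = 3)
  tab$target_id[1] <- "hERG"
  cur <- curate_activity_records(tab[1:4, ], anti_targets = "hERG")
  expect_false("hERG" %in% cur$target_id)
  cur2 <- curate_activity_records(tab[1:4, ],
    interference_predicate = function(df) df$compound_id == "OK2")
  expect_false("OK2" %in% cur2$compound_id)
})

test_that("duplicate (compound, target) records collapse to median potency", {
  tab <- generate_fixture_activity_table(n_clean = 1, seed = 4)[1, ]
  dup <- rbind(tab, tab, tab)
  dup$standard_value_nM <- c(10, 100, 30)
  cur <- curate_activity_records(dup)
  expect_equal(nrow(cur), 1L)
  expect_equal(cur$standard_value_nM, 30)
})

test_that("potency direction is configurable", {
  tab <- generate_fixture_activity_table(n_clean = 1, seed = 5)[1, ]
  tab$standard_value_nM <- 50000
  expect_equal(nrow(curate_activity_records(tab)), 0L)
  expect_equal(nrow(curate_activity_records(tab, potency_direction = "keep_weak")), 1L)
})

test_that("fixture series are deterministic, unique and share cores", {
  a <- generate_fixture_series(1, 3, seed = 7)
  expect_length(a, 3L)
  expect_length(unique(vapply(a, `[[`, "", "smiles")), 3L)
  expect_identical(unique(vapply(a, `[[`, "", "activity_class")), "S1")

  b1 <- generate_fixture_series(5, 4, seed = 1)
  b2 <- generate_fixture_series(5, 4, seed = 1)
  expect_identical(vapply(b1, `[[`, "", "smiles"),
                   vapply(b2, `[[`, "", "smiles"))
  expect_length(unique(vapply(b1, `[[`, "", "smiles")), 20L)
})
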
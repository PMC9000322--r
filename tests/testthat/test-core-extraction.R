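test_that("single-cut enumeration matches hand fragmentation of toluene", {
  tol <- ref_mols()[["tol"]]
  cuts <- enumerate_cuts(tol)
  expect_length(cuts, 1L)
  expect_identical(cuts[[1]]$core_smiles, "c1ccccc1")
  expect_identical(cuts[[1]]$substituent_smiles, "C")
})

test_that("molecules without rings yield no cuts", {
  eth <- standardize("CC")[[1]]
  expect_length(enumerate_cuts(eth), 0L)
})

test_that("the 2:1 size ratio rejects the quaternary cut of tert-butylbenzene", {
  tbb <- ref_mols()[["tbb"]]
  cuts <- enumerate_cuts(tbb)
  cores <- vapply(cuts, `[[`, "", "core_smiles")
  expect_false("c1ccccc1" %in% cores)   # benzene(6) < 2 x C4(4)
  # every admitted cut satisfies the invariant
  for (cut in cuts) {
    nc <- length(cut$core_atoms)
    ns <- sum(lengths(cut$substituent_atoms))
    expect_gte(nc, 2 * ns)
  }
})

test_that("cut components partition the molecule and recombine to the parent", {
  for (mol in toy_mols()[1:5]) {
    cuts <- enumerate_cuts(mol, compute_smiles = FALSE)
    for (cut in cuts) {
      atoms <- sort(c(cut$core_atoms, unlist(cut$substituent_atoms)))
      expect_identical(atoms, seq_len(nrow(mol$atoms)))
      whole <- csfpr:::subgraph_smiles(mol, list(w = atoms))
      expect_identical(unname(whole), mol$smiles)
    }
  }
})

test_that("capacity guard trips on highly cuttable molecules", {
  m <- standardize("CCCCCCCCCCc1ccccc1CCCCCCCCCC")[[1]]
  expect_error(enumerate_cuts(m, max_candidate_bonds = 5L), "capacity")
})

test_that("analogue series recover the designed fixture cores", {
  mols <- generate_fixture_series(5, 4, seed = 21)
  series <- build_analogue_series(mols)
  expect_true(all(series$n_members >= 2))
  # every designed series appears as a core whose members are exactly its 4
  # compounds
  cls <- vapply(mols, `[[`, "", "activity_class")
  for (s in unique(cls)) {
    ids <- paste(sort(vapply(mols[cls == s], `[[`, "", "id")), collapse = ";")
    expect_true(ids %in% series$member_ids)
  }
  expect_gte(sum(series$n_members == 4), 5L)
})

test_that("two singleton compounds yield no analogue-series cores", {
  two <- standardize(c("Cc1ccccc1", "CCC1CCNCC1"), ids = c("a", "b"))
  expect_equal(nrow(build_analogue_series(two)), 0L)
})

test_that("core membership is invariant under input ordering", {
  mols <- generate_fixture_series(4, 3, seed = 23)
  fwd <- build_analogue_series(mols)
  rev_ <- build_analogue_series(mols[rev(seq_along(mols))])
  expect_identical(fwd, rev_)
})

test_that("generalized cores are hydrogen-capped (no attachment placeholders)", {
  series <- build_analogue_series(generate_fixture_series(3, 3, seed = 25))
  expect_false(any(grepl("\\*|\\[\\*\\]", series$core_smiles)))
  expect_true(all(vapply(standardize(series$core_smiles),
                         function(m) any(csfpr:::ring_bonds(m)), NA)))
})
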
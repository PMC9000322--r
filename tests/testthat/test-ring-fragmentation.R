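test_that("ring systems are split at acyclic bonds, fused systems kept whole", {
  naph <- extract_ring_systems(ref_mols()[["naph"]])
  expect_length(naph, 1L)
  expect_identical(naph[[1]]$kind, "fused")

  bip <- extract_ring_systems(ref_mols()[["bip"]])
  expect_length(bip, 2L)
  expect_identical(unique(vapply(bip, `[[`, "", "kind")), "single")

  expect_error(extract_ring_systems(standardize("CCO")[[1]]), "no rings")
})

test_that("fused decomposition keeps fused-context states (model fragments)", {
  naph_f <- extract_ring_systems(ref_mols()[["naph"]])[[1]]
  singles <- decompose_fused(naph_f)
  expect_length(singles, 2L)
  expect_true(all(vapply(singles, `[[`, NA, "is_model")))
  # aromatic states retained: patterns are aromatic six-rings
  expect_true(all(grepl("c\\^2", vapply(singles, `[[`, "", "pattern"))))

  ind_f <- extract_ring_systems(ref_mols()[["ind"]])[[1]]
  ind_s <- decompose_fused(ind_f)
  expect_length(ind_s, 2L)
  sizes <- vapply(ind_s, function(f) nrow(f$atoms), 1L)
  expect_setequal(sizes, c(5L, 6L))
  expect_true(any(grepl("n\\^2", vapply(ind_s, `[[`, "", "pattern"))))
  expect_true(all(vapply(ind_s, `[[`, NA, "is_model")))

  dec_f <- extract_ring_systems(ref_mols()[["dec"]])[[1]]
  dec_s <- decompose_fused(dec_f)
  expect_false(any(vapply(dec_s, `[[`, NA, "is_model")))  # sp3 fusion atoms
  expect_true(all(grepl("C\\^3", vapply(dec_s, `[[`, "", "pattern"))))

  expect_error(decompose_fused(extract_ring_systems(ref_mols()[["tol"]])[[1]]),
               "fused")
})

test_that("every emitted fragment re-matches its parent structure", {
  for (id in c("naph", "ind", "dec", "bip", "spiro")) {
    mol <- ref_mols()[[id]]
    tgt <- csfpr:::match_target(mol)
    for (f in extract_ring_systems(mol)) {
      expect_true(csfpr:::match_substructure(csfpr:::match_query(f), tgt),
                  label = paste(id, f$pattern))
      if (f$kind == "fused") {
        for (s in decompose_fused(f))
          expect_true(csfpr:::match_substructure(csfpr:::match_query(s), tgt),
                      label = paste(id, "single", s$pattern))
      }
    }
  }
})

test_that("decomposition count equals the smallest-ring count", {
  mols <- toy_mols()
  checked <- 0L
  for (mol in mols[1:20]) {
    for (f in extract_ring_systems(mol)) {
      if (f$kind != "fused") next
      n_rings <- nrow(f$bonds) - nrow(f$atoms) + 1L
      expect_length(decompose_fused(f), n_rings)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)
})

test_that("fragmentation is invariant under atom renumbering", {
  a <- standardize("c1ccc2c(c1)cc[nH]2")[[1]]     # indole, two spellings
  b <- standardize("[nH]1ccc2c1cccc2")[[1]]
  pa <- sort(vapply(extract_ring_systems(a), `[[`, "", "pattern"))
  pb <- sort(vapply(extract_ring_systems(b), `[[`, "", "pattern"))
  expect_identical(pa, pb)
  da <- sort(vapply(decompose_fused(extract_ring_systems(a)[[1]]), `[[`, "", "pattern"))
  db <- sort(vapply(decompose_fused(extract_ring_systems(b)[[1]]), `[[`, "", "pattern"))
  expect_identical(da, db)
})

test_that("spiro unions are fused by default and separable on request", {
  spiro <- ref_mols()[["spiro"]]
  merged <- extract_ring_systems(spiro)
  expect_length(merged, 1L)
  expect_identical(merged[[1]]$kind, "fused")
  expect_length(decompose_fused(merged[[1]]), 2L)
  apart <- extract_ring_systems(spiro, merge_spiro = FALSE)
  expect_length(apart, 2L)
  expect_identical(unique(vapply(apart, `[[`, "", "kind")), "single")
})

test_that("ring catalogs count single, fused and decomposition fragments", {
  rcat <- toy_build()
  expect_true(all(c("pattern", "kind", "is_model", "frequency") %in%
                    names(rcat$rings_single)))
  expect_true(all(rcat$rings_single$kind == "single"))
  expect_true(all(rcat$rings_fused$kind == "fused"))
  expect_true(any(rcat$rings_single$is_model))
  expect_true(all(rcat$rings_single$frequency >= 1))
})
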
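test_that("library size is the sum of category quotas", {
  b <- toy_build()
  lib <- assemble_library(b$rings_single, b$rings_fused, b$substituents,
                          n_single = 2, n_fused = 2, n_subs = 4)
  expect_equal(lib$L, 8L)
  expect_identical(lib$kind, c(rep("single", 2), rep("fused", 2),
                               rep("substituent", 4)))
  expect_error(assemble_library(b$rings_single[0, ], b$rings_fused,
                                b$substituents), "empty")
})

test_that("fused rings close over their recorded decomposition rings", {
  ex <- closure_example()
  fused_bit <- which(ex$lib$kind == "fused")
  single_bit <- which(ex$lib$kind == "single")
  expect_true(single_bit %in% ex$lib$closure[[fused_bit]])
})

test_that("a substituent containing two recorded substituents sets three bits", {
  ex <- closure_example()
  fp <- compute_csfp(ex$mol, ex$lib)
  sub_bits <- which(fp$bits & ex$lib$kind == "substituent")
  expect_length(sub_bits, 3L)                  # propoxy + ethyl + methyl
  expect_equal(feature_count(fp), 5L)          # + fused naphthalene + six-ring
})

test_that("molecules matching no fragment give the permitted zero vector", {
  ex <- closure_example()
  cyp <- standardize("C1CC1")[[1]]             # cyclopropane: not recorded
  fp <- compute_csfp(cyp, ex$lib)
  expect_equal(feature_count(fp), 0L)
  expect_equal(bit_density(fp), 0)
  expect_equal(nrow(fp$provenance), 0L)
})

test_that("provenance explains every set bit and closure bits have ancestors", {
  lib <- toy_library()
  for (mol in toy_mols()[1:10]) {
    fp <- compute_csfp(mol, lib)
    expect_equal(sum(fp$bits), nrow(fp$provenance))
    direct <- fp$provenance$bit[fp$provenance$via == "direct"]
    clos <- fp$provenance$bit[fp$provenance$via == "closure"]
    for (b in clos)
      expect_true(any(vapply(direct, function(d) b %in% lib$closure[[d]], NA)))
  }
})

test_that("closure only widens the bit set (monotonicity)", {
  lib <- toy_library()
  nolib <- lib; nolib$closure <- rep(list(integer()), lib$L)
  for (mol in toy_mols()[1:10]) {
    with_c <- which(compute_csfp(mol, lib)$bits)
    without <- which(compute_csfp(mol, nolib)$bits)
    expect_true(all(without %in% with_c))
  }
})

test_that("compute_csfp agrees with the brute-force oracle on a toy library", {
  lib <- toy_library()
  expect_lte(lib$L, 30L)
  for (mol in toy_mols()[seq(1, 80, by = 4)]) {
    expect_identical(which(compute_csfp(mol, lib)$bits > 0),
                     brute_csfp_bits(mol, lib),
                     label = mol$id)
  }
})

test_that("tanimoto follows the set formula with the zero-vector convention", {
  a <- rep(0L, 10); a[c(1, 2, 3)] <- 1L
  b <- rep(0L, 10); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, rep(0L, 10)), 0)
  expect_equal(tanimoto(rep(0L, 10), rep(0L, 10)), 0)
  d <- rep(0L, 10); d[5:6] <- 1L
  expect_equal(tanimoto(a, d), 0)
  expect_error(tanimoto(a, rep(0L, 9)), "length")
  # symmetry and matrix consistency
  M <- rbind(a, b, d)
  K <- tanimoto_matrix(M, M)
  expect_equal(K, t(K))
  expect_equal(K[1, 2], 0.5)
  expect_equal(diag(K), c(a = 1, b = 1, d = 1), ignore_attr = TRUE)
})

test_that("one minus Tanimoto behaves like a distance on binary vectors", {
  set.seed(1)
  X <- matrix(rbinom(30 * 16, 1, 0.4), 30)
  K <- tanimoto_matrix(X, X)
  D <- 1 - K
  for (rep in 1:200) {
    ijk <- sample(30, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("feature counts and bit density are popcount-based", {
  v <- rep(0L, 1000); v[1:28] <- 1L
  expect_equal(feature_count(v), 28)
  expect_equal(bit_density(v), 2.8)
  M <- rbind(v, rep(0L, 1000))
  expect_equal(feature_count(M), c(28, 0), ignore_attr = TRUE)
})

test_that("median CSFP feature count sits below MACCS and ECFP4", {
  mols <- full_mols()[1:100]
  med_c <- median(feature_count(compute_csfp_matrix(mols, full_library())))
  med_m <- median(feature_count(maccs_fp(mols)))
  med_e <- median(feature_count(ecfp4_fp(mols)))
  expect_lt(med_c, med_m)
  expect_lt(med_c, med_e)
})

test_that("library JSON serialization round-trips", {
  lib <- toy_library()
  path <- tempfile(fileext = ".json")
  write_library(lib, path)
  back <- read_library(path)
  expect_identical(back$pattern, lib$pattern)
  expect_identical(back$kind, lib$kind)
  expect_identical(back$closure, lib$closure)
  mol <- toy_mols()[[3]]
  expect_identical(compute_csfp(mol, back)$bits, compute_csfp(mol, lib)$bits)
})

test_that("fragment patterns are self-describing", {
  lib <- toy_library()
  for (i in seq_len(lib$L)) {
    f2 <- csfpr:::fragment_from_pattern(lib$pattern[i], lib$kind[i])
    expect_identical(csfpr:::canonical_fragment_form(f2$atoms, f2$bonds)$pattern,
                     lib$pattern[i])
  }
})
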
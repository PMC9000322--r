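# Shared fixtures, built once per test run and cached.

.tcache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.tcache[[name]])) .tcache[[name]] <- force(expr)
  .tcache[[name]]
}

# small molecule set with well-understood structures
ref_mols <- function() cached("ref_mols", standardize(
  c(naph = "c1ccc2ccccc2c1", bip = "c1ccc(cc1)-c1ccccc1",
    ind = "c1ccc2c(c1)cc[nH]2", dec = "C1CCC2CCCCC2C1",
    tol = "Cc1ccccc1", tbb = "CC(C)(C)c1ccccc1",
    spiro = "C1CCC2(C1)CCCCC2", anisole = "COc1ccccc1",
    pyridine = "c1ccncc1", cyclohexane = "C1CCCCC1"),
  ids = c("naph", "bip", "ind", "dec", "tol", "tbb", "spiro", "anisole",
          "pyridine", "cyclohexane")))

# 80-compound analogue-series collection + small toy library
toy_mols <- function() cached("toy_mols", generate_fixture_series(20, 4, seed = 11))

toy_build <- function() cached("toy_build",
  csfp_build_library(toy_mols(), n_single = 8, n_fused = 8, n_subs = 14))

toy_library <- function() toy_build()$library

# full-scale fixture collection and default 1000-bit library (expensive;
# shared by the acceptance suite)
full_mols <- function() cached("full_mols", generate_fixture_series(300, 3, seed = 42))

full_build <- function() cached("full_build", csfp_build_library(full_mols()))

full_library <- function() full_build()$library

# analogue-series activity class and decoy background for benchmark tests
bench_class <- function() cached("bench_class",
  generate_fixture_series(1, 100, seed = 77, n_sites = 2))

bench_core_patterns <- function() cached("bench_core_patterns", {
  unique(unlist(lapply(extract_ring_systems(bench_class()[[1]]), function(f)
    c(f$pattern, if (f$kind == "fused")
      vapply(decompose_fused(f), `[[`, "", "pattern")))))
})

bench_decoys <- function() cached("bench_decoys",
  generate_fixture_compounds(1000, seed = 78,
                             exclude_patterns = bench_core_patterns()))

bench_class_fps <- function() cached("bench_class_fps",
  compute_csfp_matrix(bench_class(), full_library()))

bench_decoy_fps <- function() cached("bench_decoy_fps",
  compute_csfp_matrix(bench_decoys(), full_library()))
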
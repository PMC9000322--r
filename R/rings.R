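# Ring-system extraction and decomposition.
#
# Cores are decomposed by first deleting all acyclic bonds and acyclic atoms:
# each remaining connected component is a ring system. Components made of a
# single smallest ring are recorded as chemically intact single rings; fused
# components (>= 2 smallest rings sharing a bond, or an atom for spiro unions)
# are recorded whole and additionally decomposed into their individual rings.
# Rings cut out of a fused system keep the aromaticity/hybridization states
# their atoms had in the fused context ("model fragments"), so they re-match
# inside larger ring systems even when no isolated molecule carries that
# electronic state.

ring_fragment_from_system <- function(mol, system, kind) {
  idx <- system$atoms
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  b <- mol$bonds[system$bond_rows, , drop = FALSE]
  atoms <- data.frame(elem = mol$atoms$elem[idx], arom = mol$atoms$arom[idx],
                      hyb = mol$atoms$hyb[idx], deg = NA_integer_,
                      attach = FALSE, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = remap[b$a1], a2 = remap[b$a2],
                      code = bond_code(b$order, b$arom), stringsAsFactors = FALSE)
  new_fragment(atoms, bonds, kind = kind, is_model = FALSE)
}

#' Extract ring systems from a core structure
#'
#' Deletes all acyclic bonds and atoms; each remaining connected component is
#' emitted as one ring fragment: `kind = "fused"` when it contains two or more
#' smallest rings (rings sharing a bond, or an atom when `merge_spiro`), else
#' `kind = "single"`. Rings joined only by acyclic linker bonds (e.g.
#' biphenyl) are separate single rings, not fused systems.
#'
#' @param mol a `csfp_mol` (typically a parsed core structure).
#' @param merge_spiro treat spiro unions (rings sharing one atom) as fused.
#' @return list of `csfp_fragment` objects.
#' @export
extract_ring_systems <- function(mol, merge_spiro = TRUE) {
  stopifnot(inherits(mol, "csfp_mol"))
  systems <- ring_systems(mol, merge_spiro = merge_spiro)
  if (length(systems) == 0L)
    stop("molecule contains no rings: ", mol$smiles)
  lapply(systems, function(s) {
    n_rings <- length(s$bond_rows) - length(s$atoms) + 1L
    ring_fragment_from_system(mol, s, kind = if (n_rings >= 2L) "fused" else "single")
  })
}

#' Decompose a fused ring system into single-ring fragments
#'
#' Returns one fragment per smallest ring of the fused system. Each ring keeps
#' the element, aromaticity and hybridization states of its atoms as they were
#' inside the fused system, so each emitted fragment re-matches its parent. A
#' fragment is flagged `is_model` when any fusion atom (an atom shared with
#' another smallest ring) is aromatic or sp2: such a ring's electronic state
#' depends on the fused environment and cannot exist as an isolated molecule.
#'
#' @param fused a `csfp_fragment` with `kind == "fused"`.
#' @return list of single-ring `csfp_fragment` objects.
#' @export
decompose_fused <- function(fused) {
  stopifnot(inherits(fused, "csfp_fragment"))
  if (fused$kind != "fused") stop("decompose_fused() requires a fused fragment")
  pseudo <- list(atoms = fused$atoms, bonds = fused$bonds)
  system <- list(atoms = seq_len(nrow(fused$atoms)),
                 bond_rows = seq_len(nrow(fused$bonds)))
  rings <- sssr_system(pseudo, system)
  ring_atoms <- lapply(rings, function(br)
    sort(unique(c(fused$bonds$a1[br], fused$bonds$a2[br]))))
  out <- vector("list", length(rings))
  for (i in seq_along(rings)) {
    idx <- ring_atoms[[i]]
    others <- unique(unlist(ring_atoms[-i]))
    fusion <- intersect(idx, others)
    is_model <- length(fusion) > 0 &&
      any(fused$atoms$arom[fusion] | fused$atoms$hyb[fusion] == 2L)
    remap <- match(seq_len(nrow(fused$atoms)), idx)
    b <- fused$bonds[rings[[i]], , drop = FALSE]
    atoms <- data.frame(elem = fused$atoms$elem[idx], arom = fused$atoms$arom[idx],
                        hyb = fused$atoms$hyb[idx], deg = NA_integer_,
                        attach = FALSE, stringsAsFactors = FALSE)
    bonds <- data.frame(a1 = remap[b$a1], a2 = remap[b$a2], code = b$code,
                        stringsAsFactors = FALSE)
    out[[i]] <- new_fragment(atoms, bonds, kind = "single", is_model = is_model)
  }
  out
}

#' Build a frequency-ranked ring-fragment catalog from core structures
#'
#' Extracts ring systems from every core, records fused systems and single
#' rings, decomposes each fused system and records its decomposition rings in
#' the single-ring catalog as well. Frequencies count occurrences across
#' cores.
#'
#' @param core_mols a `csfp_molset` of parsed (hydrogen-capped) core
#'   structures.
#' @return list with `single` and `fused` catalog data frames
#'   (`pattern`, `kind`, `is_model`, `frequency`) and `fragments`, a
#'   pattern-keyed list of `csfp_fragment` objects.
#' @export
build_ring_catalog <- function(core_mols) {
  frags <- list()
  counts <- list(single = integer(), fused = integer())
  model_all <- logical()   # pattern is a model fragment in every occurrence
  bump <- function(f) {
    p <- f$pattern
    if (is.null(frags[[p]])) frags[[p]] <<- f
    k <- f$kind
    counts[[k]][p] <<- (if (is.na(counts[[k]][p])) 0L else counts[[k]][p]) + 1L
    prev <- model_all[p]
    model_all[p] <<- (is.na(prev) || prev) && f$is_model
  }
  for (mol in core_mols) {
    systems <- tryCatch(extract_ring_systems(mol), error = function(e) NULL)
    if (is.null(systems)) next
    for (s in systems) {
      bump(s)
      if (s$kind == "fused") for (r in decompose_fused(s)) bump(r)
    }
  }
  catalog <- function(kind) {
    cnt <- counts[[kind]]
    if (length(cnt) == 0L)
      return(data.frame(pattern = character(), kind = character(),
                        is_model = logical(), frequency = integer()))
    data.frame(pattern = names(cnt), kind = kind,
               is_model = unname(model_all[names(cnt)]),
               frequency = as.integer(cnt), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  list(single = catalog("single"), fused = catalog("fused"), fragments = frags)
}
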
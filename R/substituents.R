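# Substituent (R-group) harvesting and frequency-ranked selection.

# Build a substituent fragment from the substituent-side atoms of a cut. The
# attachment point is a wildcard atom bonded by a single non-aromatic bond;
# every real atom carries an exact heavy-atom degree (its degree within the
# substituent, counting the attachment), so an R-group pattern matches
# R-group-like occurrences and not arbitrary embeddings in rings.
substituent_fragment <- function(mol, sub_atoms, cut_bond_row) {
  idx <- sort(sub_atoms)
  b <- mol$bonds[cut_bond_row, ]
  attach_atom <- if (b$a1 %in% idx) b$a1 else b$a2
  stopifnot(attach_atom %in% idx)
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  inb <- mol$bonds[mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx, , drop = FALSE]
  deg <- tabulate(c(remap[inb$a1], remap[inb$a2]), nbins = length(idx))
  deg[remap[attach_atom]] <- deg[remap[attach_atom]] + 1L
  n <- length(idx)
  atoms <- data.frame(
    elem = c(mol$atoms$elem[idx], "*"),
    arom = c(mol$atoms$arom[idx], NA),
    hyb = NA_integer_,
    deg = c(deg, NA_integer_),
    attach = c(rep(FALSE, n), TRUE), stringsAsFactors = FALSE)
  bonds <- rbind(
    data.frame(a1 = remap[inb$a1], a2 = remap[inb$a2],
               code = bond_code(inb$order, inb$arom), stringsAsFactors = FALSE),
    data.frame(a1 = remap[attach_atom], a2 = n + 1L, code = "1",
               stringsAsFactors = FALSE))
  new_fragment(atoms, bonds, kind = "substituent")
}

# Unsubstituted benzene is only admitted as a ring fragment, never as a
# substituent; hydrogen cannot arise (only heavy-atom bonds are cut).
is_benzene_substituent <- function(frag) {
  real <- !frag$atoms$attach
  sum(real) == 6L && all(frag$atoms$elem[real] == "C") &&
    all(frag$atoms$arom[real]) && sum(frag$bonds$code == "ar") == 6L
}

#' Harvest substituent fragments from fragmentation products
#'
#' Collects the substituent-side products of systematic bond cuts (and,
#' optionally, of a retrosynthetic-rule cutter) across a compound set, merges
#' duplicates by canonical pattern summing frequencies, and applies the
#' exclusion rules: the benzene ring and the hydrogen atom are never
#' substituents. Frequencies are counted per occurrence.
#'
#' @param mols a `csfp_molset`.
#' @param cuts_per_mol optional precomputed list of [enumerate_cuts()] results
#'   aligned with `mols` (computed on the fly otherwise).
#' @param retro_cutter optional function `f(mol)` returning cuts in the
#'   [enumerate_cuts()] shape; its products are merged in with source
#'   `"retrosynthetic"` (see [retro_cuts()] for the bundled rule set).
#' @param max_cuts,ratio passed to [enumerate_cuts()] when cuts are computed.
#' @return catalog data frame (`pattern`, `frequency`, `source`), ordered by
#'   decreasing frequency then pattern.
#' @export
harvest_substituents <- function(mols, cuts_per_mol = NULL, retro_cutter = NULL,
                                 max_cuts = 5L, ratio = 2.0) {
  freq <- list(random_cut = integer(), retrosynthetic = integer())
  add <- function(src, frag) {
    if (is_benzene_substituent(frag)) return()
    p <- frag$pattern
    freq[[src]][p] <<- (if (is.na(freq[[src]][p])) 0L else freq[[src]][p]) + 1L
  }
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    cuts <- if (!is.null(cuts_per_mol)) cuts_per_mol[[i]] else
      enumerate_cuts(mol, max_cuts = max_cuts, ratio = ratio,
                     compute_smiles = FALSE)
    for (cut in cuts)
      for (j in seq_along(cut$substituent_atoms))
        add("random_cut",
            substituent_fragment(mol, cut$substituent_atoms[[j]],
                                 cut$bond_rows[j]))
    if (!is.null(retro_cutter)) {
      for (cut in retro_cutter(mol))
        for (j in seq_along(cut$substituent_atoms))
          add("retrosynthetic",
              substituent_fragment(mol, cut$substituent_atoms[[j]],
                                   cut$bond_rows[j]))
    }
  }
  pats <- sort(unique(c(names(freq$random_cut), names(freq$retrosynthetic))))
  if (length(pats) == 0L)
    return(data.frame(pattern = character(), frequency = integer(),
                      source = character()))
  f1 <- freq$random_cut[pats]; f1[is.na(f1)] <- 0L
  f2 <- freq$retrosynthetic[pats]; f2[is.na(f2)] <- 0L
  src <- ifelse(f1 > 0 & f2 > 0, "both",
                ifelse(f1 > 0, "random_cut", "retrosynthetic"))
  out <- data.frame(pattern = pats, frequency = as.integer(f1 + f2),
                    source = src, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retrosynthetic-rule bond cutter
#'
#' A deliberately small RECAP/BRICS-flavored rule set usable as the
#' `retro_cutter` hook of [harvest_substituents()]: acyclic single bonds at
#' amide (C(=O)-N), ester (C(=O)-O), amine (C-N), ether (C-O) and
#' ring-atom-to-substituent positions are cut one at a time; the smaller side
#' of each cut is taken as the substituent product.
#'
#' @param mol a `csfp_mol`.
#' @return list of cuts in the [enumerate_cuts()] shape (without SMILES).
#' @export
retro_cuts <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  rb <- ring_bonds(mol)
  at <- mol$atoms
  carbonyl <- rep(FALSE, nrow(at))
  dbl <- mol$bonds[mol$bonds$order == 2L & !mol$bonds$arom, , drop = FALSE]
  for (j in seq_len(nrow(dbl))) {
    if (at$elem[dbl$a1[j]] == "C" && at$elem[dbl$a2[j]] == "O")
      carbonyl[dbl$a1[j]] <- TRUE
    if (at$elem[dbl$a2[j]] == "C" && at$elem[dbl$a1[j]] == "O")
      carbonyl[dbl$a2[j]] <- TRUE
  }
  in_ring_atom <- rep(FALSE, nrow(at))
  in_ring_atom[c(mol$bonds$a1[rb], mol$bonds$a2[rb])] <- TRUE
  g <- mol_graph(mol)
  out <- list()
  for (k in which(!rb & mol$bonds$order == 1L & !mol$bonds$arom)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    ea <- at$elem[a]; eb <- at$elem[b]
    rule <- (carbonyl[a] && eb %in% c("N", "O")) ||
      (carbonyl[b] && ea %in% c("N", "O")) ||
      (ea == "C" && eb %in% c("N", "O")) || (eb == "C" && ea %in% c("N", "O")) ||
      xor(in_ring_atom[a], in_ring_atom[b])
    if (!rule) next
    g2 <- igraph::delete_edges(g, k)
    memb <- igraph::components(g2)$membership
    side_a <- which(memb == memb[a]); side_b <- which(memb == memb[b])
    sub <- if (length(side_a) <= length(side_b)) side_a else side_b
    if (length(sub) > nrow(at) / 2) next
    out[[length(out) + 1L]] <- list(bond_rows = k, substituent_atoms = list(sub))
  }
  out
}

#' Select the top-n most frequent fragments from a catalog
#'
#' Deterministic top-n by frequency with ties broken by pattern
#' (lexicographic). When the catalog holds fewer than `n` entries all are
#' returned with a warning and the realized size is recorded by the caller.
#'
#' @param catalog data frame with `pattern` and `frequency` columns.
#' @param n number of fragments to keep.
#' @return the selected rows, in rank order.
#' @export
select_top <- function(catalog, n) {
  stopifnot(n >= 1L, all(c("pattern", "frequency") %in% names(catalog)))
  ord <- order(-catalog$frequency, catalog$pattern)
  sel <- catalog[ord, , drop = FALSE]
  if (nrow(sel) < n)
    warning("catalog holds ", nrow(sel), " fragments, fewer than requested n = ", n)
  out <- utils::head(sel, n)
  rownames(out) <- NULL
  out
}
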
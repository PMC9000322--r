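# Systematic exocyclic-bond fragmentation (compound-core relationships) and
# analogue-series extraction.
#
# A cut removes 1..max_cuts acyclic single bonds between heavy atoms. Because
# every such bond is a bridge, removing k of them always yields k+1 connected
# components; a combination is admitted when one component (the core) touches
# every cut bond and each remaining component (a substituent) touches exactly
# one. The core must contain a ring and be at least `ratio` times as large
# (heavy atoms) as all substituents combined. The core is generalized by
# hydrogen-capping its open substitution sites, which happens naturally when
# the core subgraph is re-perceived as a molecule.

#' Enumerate valid core/substituent fragmentations of a molecule
#'
#' All combinations of 1 to `max_cuts` acyclic single bonds are considered;
#' each admitted combination yields one ring-containing core and one
#' substituent per cut bond, subject to the core-to-substituent heavy-atom
#' size ratio.
#'
#' @param mol a `csfp_mol`.
#' @param max_cuts maximum number of bonds cut simultaneously (1-5).
#' @param ratio minimum core : combined-substituent heavy-atom ratio.
#' @param compute_smiles attach hydrogen-capped canonical SMILES of core and
#'   substituents (one Open Babel call; disable for bulk use).
#' @param max_candidate_bonds guard against combinatorial explosion: molecules
#'   with more cuttable bonds raise a capacity error.
#' @return list of cuts; each has `bond_rows` (indices into `mol$bonds`),
#'   `core_atoms`, `substituent_atoms` (list, one per cut), and when requested
#'   `core_smiles` / `substituent_smiles`. Molecules without rings yield an
#'   empty list.
#' @examples
#' tol <- standardize("Cc1ccccc1")[[1]]
#' cuts <- enumerate_cuts(tol)
#' cuts[[1]]$core_smiles        # "c1ccccc1"
#' @export
enumerate_cuts <- function(mol, max_cuts = 5L, ratio = 2.0,
                           compute_smiles = TRUE, max_candidate_bonds = 32L) {
  stopifnot(inherits(mol, "csfp_mol"), max_cuts >= 1L, ratio > 0)
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  rb <- ring_bonds(mol)
  if (!any(rb)) return(list())     # no ring-containing core possible
  cand <- which(!rb & mol$bonds$order == 1L & !mol$bonds$arom)
  if (length(cand) == 0L) return(list())
  if (length(cand) > max_candidate_bonds)
    stop("capacity: ", length(cand), " cuttable bonds exceed max_candidate_bonds (",
         max_candidate_bonds, ") for ", mol$id)

  # block tree: components after removing all candidate bonds
  natom <- nrow(mol$atoms)
  g0 <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2),
                                    directed = FALSE)
  g_blocks <- igraph::delete_edges(g0, cand)
  memb <- igraph::components(g_blocks)$membership       # atom -> block
  n_blocks <- max(memb)
  block_w <- tabulate(memb, nbins = n_blocks)
  block_has_ring <- rep(FALSE, n_blocks)
  if (any(rb)) block_has_ring[unique(memb[mol$bonds$a1[rb]])] <- TRUE
  # tree edges over blocks, one per candidate bond
  eb1 <- memb[mol$bonds$a1[cand]]
  eb2 <- memb[mol$bonds$a2[cand]]
  total_w <- natom

  # union-find over the block tree (small; avoids per-combination graph
  # construction in the hot loop)
  uf_components <- function(drop) {
    parent <- seq_len(n_blocks)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in seq_along(cand)) {
      if (e %in% drop) next
      ra <- find(eb1[e]); rb <- find(eb2[e])
      if (ra != rb) parent[ra] <- rb
    }
    roots <- vapply(seq_len(n_blocks), function(x) as.integer(find(x)), 1L)
    match(roots, unique(roots))
  }
  cuts <- list()
  for (k in seq_len(min(max_cuts, length(cand)))) {
    for (combo in utils::combn(length(cand), k, simplify = FALSE)) {
      cm <- uf_components(combo)                         # block -> part
      p1 <- cm[eb1[combo]]; p2 <- cm[eb2[combo]]
      inc <- tabulate(c(p1, p2), nbins = max(cm))        # cuts touching part
      for (core_part in which(inc == k)) {               # k = 1: both sides tried
        if (any(inc[-core_part] != 1L)) next
        core_blocks <- which(cm == core_part)
        if (!any(block_has_ring[core_blocks])) next
        core_w <- sum(block_w[core_blocks])
        if (core_w < ratio * (total_w - core_w)) next
        core_atoms <- which(memb %in% core_blocks)
        sub_atoms <- lapply(seq_along(combo), function(j) {
          part <- if (p1[j] == core_part) p2[j] else p1[j]
          which(memb %in% which(cm == part))
        })
        cuts[[length(cuts) + 1L]] <- list(
          bond_rows = cand[combo],
          core_atoms = core_atoms,
          substituent_atoms = sub_atoms)
      }
    }
  }
  if (compute_smiles && length(cuts) > 0) {
    sets <- list(); idx <- character()
    for (i in seq_along(cuts)) {
      sets[[paste0("c", i)]] <- cuts[[i]]$core_atoms
      for (j in seq_along(cuts[[i]]$substituent_atoms))
        sets[[paste0("s", i, "_", j)]] <- cuts[[i]]$substituent_atoms[[j]]
    }
    smi <- subgraph_smiles(mol, sets)
    for (i in seq_along(cuts)) {
      cuts[[i]]$core_smiles <- unname(smi[paste0("c", i)])
      cuts[[i]]$substituent_smiles <-
        unname(smi[paste0("s", i, "_", seq_along(cuts[[i]]$substituent_atoms))])
    }
  }
  cuts
}

#' Group compounds into analogue series by shared generalized core
#'
#' Every admissible fragmentation core of every compound is generalized by
#' hydrogen-capping and canonicalized; compounds sharing a core form an
#' analogue series. Only ring-containing cores shared by at least
#' `min_members` compounds are returned, sorted by decreasing series size with
#' ties broken by core SMILES.
#'
#' @param mols a `csfp_molset`.
#' @param max_cuts,ratio passed to [enumerate_cuts()].
#' @param min_members minimum series size (2 for analogue-series cores).
#' @param per_compound `"all"` records every valid core of a compound (used
#'   for library statistics); `"largest"` keeps only its largest core.
#' @param cuts_per_mol optional precomputed [enumerate_cuts()] results
#'   aligned with `mols`.
#' @return data frame with `core_smiles`, `n_members`, `member_ids`
#'   (semicolon-joined), ordered as above.
#' @export
build_analogue_series <- function(mols, max_cuts = 5L, ratio = 2.0,
                                  min_members = 2L,
                                  per_compound = c("all", "largest"),
                                  cuts_per_mol = NULL) {
  per_compound <- match.arg(per_compound)
  if (length(mols) == 0L)
    return(data.frame(core_smiles = character(), n_members = integer(),
                      member_ids = character()))
  pairs <- list()
  for (mi in seq_along(mols)) {
    mol <- mols[[mi]]
    cuts <- if (!is.null(cuts_per_mol)) cuts_per_mol[[mi]] else
      enumerate_cuts(mol, max_cuts = max_cuts, ratio = ratio,
                     compute_smiles = FALSE)
    if (length(cuts) == 0L) next
    sets <- lapply(cuts, `[[`, "core_atoms")
    if (per_compound == "largest")
      sets <- sets[which.max(lengths(sets))]
    names(sets) <- paste0("c", seq_along(sets))
    smi <- unique(unname(subgraph_smiles(mol, sets)))
    pairs[[mol$id]] <- smi
  }
  if (length(pairs) == 0L)
    return(data.frame(core_smiles = character(), n_members = integer(),
                      member_ids = character()))
  df <- data.frame(id = rep(names(pairs), lengths(pairs)),
                   core = unlist(pairs, use.names = FALSE),
                   stringsAsFactors = FALSE)
  agg <- split(df$id, df$core)
  out <- data.frame(core_smiles = names(agg),
                    n_members = lengths(lapply(agg, unique)),
                    member_ids = vapply(agg, function(x)
                      paste(sort(unique(x)), collapse = ";"), ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n_members >= min_members, , drop = FALSE]
  out <- out[order(-out$n_members, out$core_smiles), , drop = FALSE]
  rownames(out) <- NULL
  out
}
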
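# Internal graph machinery: ring perception, SSSR, fragment patterns and
# hybridization-aware substructure matching.
#
# Fragments are represented as constraint graphs, not molecules: every atom
# carries the element, aromaticity and (for ring fragments) hybridization state
# it had in its source context, which is what lets "model" ring fragments --
# e.g. one ring of naphthalene -- match inside larger fused systems even though
# they cannot exist as isolated molecules. Substituent atoms instead carry an
# exact heavy-atom degree so an R-group matches as an R-group (a methyl
# pattern does not fire on a ring CH2). Matching itself is delegated to
# igraph's LAD solver on a bipartite atom/bond-node encoding, with per-node
# compatibility domains carrying all chemical constraints.

mol_graph <- function(mol) {
  igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2), directed = FALSE)
}

# logical vector over bond rows: bond participates in a ring
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nb)
  res[as.integer(br)] <- FALSE
  res
}

# Ring systems: cyclic biconnected blocks of the molecular graph (rings
# sharing a bond are one block; a spiro atom is an articulation point, so
# spiro-joined rings are separate blocks). With merge_spiro = TRUE (default)
# blocks sharing an atom are merged, treating spiro unions as fused.
ring_systems <- function(mol, merge_spiro = TRUE) {
  if (nrow(mol$bonds) == 0L) return(list())
  g <- mol_graph(mol)
  bc <- igraph::biconnected_components(g)
  systems <- list()
  for (es in bc$component_edges) {
    rows <- sort(as.integer(es))
    verts <- sort(unique(c(mol$bonds$a1[rows], mol$bonds$a2[rows])))
    if (length(rows) < length(verts)) next     # acyclic block (a bridge)
    systems[[length(systems) + 1L]] <- list(atoms = verts, bond_rows = rows)
  }
  if (length(systems) == 0L) return(list())
  if (merge_spiro && length(systems) > 1L) {
    repeat {
      merged <- FALSE
      for (i in seq_along(systems)) {
        for (j in seq_along(systems)) {
          if (j <= i) next
          if (length(intersect(systems[[i]]$atoms, systems[[j]]$atoms)) > 0) {
            systems[[i]] <- list(
              atoms = sort(union(systems[[i]]$atoms, systems[[j]]$atoms)),
              bond_rows = sort(c(systems[[i]]$bond_rows, systems[[j]]$bond_rows)))
            systems <- systems[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  systems[order(vapply(systems, function(s) min(s$atoms), 1L))]
}

# Smallest set of smallest rings of one ring system (Horton-style minimum
# cycle basis: per-edge shortest cycles, greedily accepted under GF(2)
# independence). Returns a list of integer vectors of bond rows.
sssr_system <- function(mol, system) {
  br <- system$bond_rows
  nb <- length(br)
  atoms <- system$atoms
  n_rings <- nb - length(atoms) + 1L
  stopifnot(n_rings >= 1L)
  amap <- match(seq_len(nrow(mol$atoms)), atoms)  # mol atom -> local vertex
  el <- cbind(amap[mol$bonds$a1[br]], amap[mol$bonds$a2[br]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  # candidate cycles: for each edge, shortest path between its endpoints
  # avoiding the edge itself
  cand <- list()
  for (k in seq_len(nb)) {
    g2 <- igraph::delete_edges(g, k)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = el[k, 1], to = el[k, 2],
                                                  output = "epath"))
    ep <- sp$epath[[1]]
    if (length(ep) == 0L) next
    eid <- as.integer(ep)
    eid <- ifelse(eid >= k, eid + 1L, eid)     # re-index into g's edge ids
    # recompute against original ids: delete_edges shifts ids >= k by -1
    cyc <- sort(c(k, eid))
    cand[[length(cand) + 1L]] <- cyc
  }
  cand <- unique(cand)
  ord <- order(lengths(cand),
               vapply(cand, function(x) paste(sprintf("%04d", x), collapse = ""), ""))
  cand <- cand[ord]
  # greedy GF(2) independence over edge-incidence vectors
  basis <- list()
  chosen <- list()
  for (cyc in cand) {
    v <- rep(FALSE, nb); v[cyc] <- TRUE
    w <- v
    for (bvec in basis) {
      lead <- which(bvec)[1]
      if (w[lead]) w <- xor(w, bvec)
    }
    if (any(w)) {
      basis[[length(basis) + 1L]] <- w
      basis <- basis[order(vapply(basis, function(x) which(x)[1], 1L))]
      chosen[[length(chosen) + 1L]] <- cyc
      if (length(chosen) == n_rings) break
    }
  }
  if (length(chosen) < n_rings)
    stop("internal: SSSR basis incomplete for ring system")
  lapply(chosen, function(cyc) br[cyc])
}

# ---- fragment objects --------------------------------------------------------

bond_code <- function(order, arom) ifelse(arom, "ar", as.character(order))

atom_token <- function(elem, arom, hyb, deg, attach) {
  ifelse(attach, "*",
         paste0(ifelse(!is.na(arom) & arom, tolower(elem), elem),
                ifelse(is.na(hyb), "", paste0("^", hyb)),
                ifelse(is.na(deg), "", paste0(";D", deg))))
}

frag_bipartite <- function(natoms, bonds) {
  stopifnot(nrow(bonds) >= 1L)
  el <- cbind(c(bonds$a1, bonds$a2), rep(natoms + seq_len(nrow(bonds)), 2L))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Canonical form of a constraint graph (BLISS with attribute-derived colors);
# returns atoms/bonds reordered canonically plus the serialized pattern string.
canonical_fragment_form <- function(atoms, bonds) {
  na <- nrow(atoms)
  akeys <- paste("A", atom_token(atoms$elem, atoms$arom, atoms$hyb,
                                 atoms$deg, atoms$attach))
  bkeys <- paste("B", bonds$code)
  keys <- c(akeys, bkeys)
  colors <- match(keys, sort(unique(keys)))
  g <- frag_bipartite(na, bonds)
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  aorder <- order(lab[seq_len(na)])              # canonical atom order
  arank <- match(seq_len(na), aorder)            # old atom id -> new id
  atoms2 <- atoms[aorder, , drop = FALSE]
  rownames(atoms2) <- NULL
  b1 <- pmin(arank[bonds$a1], arank[bonds$a2])
  b2 <- pmax(arank[bonds$a1], arank[bonds$a2])
  bord <- order(b1, b2)
  bonds2 <- data.frame(a1 = b1[bord], a2 = b2[bord], code = bonds$code[bord],
                       stringsAsFactors = FALSE)
  pattern <- paste0(
    paste(atom_token(atoms2$elem, atoms2$arom, atoms2$hyb, atoms2$deg,
                     atoms2$attach), collapse = ","),
    "|",
    paste0(bonds2$a1, "-", bonds2$a2, ":", bonds2$code, collapse = ","))
  list(atoms = atoms2, bonds = bonds2, pattern = pattern)
}

# atoms: data.frame(elem, arom, hyb, deg, attach); bonds: data.frame(a1,a2,code)
new_fragment <- function(atoms, bonds, kind, is_model = FALSE) {
  stopifnot(kind %in% c("single", "fused", "substituent"))
  cf <- canonical_fragment_form(atoms, bonds)
  structure(list(atoms = cf$atoms, bonds = cf$bonds, pattern = cf$pattern,
                 kind = kind, is_model = is_model),
            class = "csfp_fragment")
}

#' @export
print.csfp_fragment <- function(x, ...) {
  cat("<csfp_fragment ", x$kind, if (x$is_model) ", model", "> ",
      x$pattern, "\n", sep = "")
  invisible(x)
}

#' @export
format.csfp_fragment <- function(x, ...) x$pattern

# Rebuild a fragment from its pattern string (inverse of serialization).
fragment_from_pattern <- function(pattern, kind, is_model = FALSE) {
  halves <- strsplit(pattern, "|", fixed = TRUE)[[1]]
  atok <- strsplit(halves[1], ",", fixed = TRUE)[[1]]
  btok <- strsplit(halves[2], ",", fixed = TRUE)[[1]]
  parse_atom <- function(t) {
    if (t == "*") return(list(elem = "*", arom = NA, hyb = NA_integer_,
                              deg = NA_integer_, attach = TRUE))
    deg <- NA_integer_
    if (grepl(";D", t, fixed = TRUE)) {
      deg <- as.integer(sub("^.*;D", "", t))
      t <- sub(";D.*$", "", t)
    }
    hyb <- NA_integer_
    if (grepl("^", t, fixed = TRUE)) {
      hyb <- as.integer(sub("^.*\\^", "", t))
      t <- sub("\\^.*$", "", t)
    }
    arom <- t == tolower(t) & grepl("^[a-z]", t)
    list(elem = if (arom) paste0(toupper(substr(t, 1, 1)), substring(t, 2)) else t,
         arom = arom, hyb = hyb, deg = deg, attach = FALSE)
  }
  al <- lapply(atok, parse_atom)
  atoms <- data.frame(elem = vapply(al, `[[`, "", "elem"),
                      arom = vapply(al, function(x) as.logical(x$arom), NA),
                      hyb = vapply(al, `[[`, NA_integer_, "hyb"),
                      deg = vapply(al, `[[`, NA_integer_, "deg"),
                      attach = vapply(al, `[[`, NA, "attach"),
                      stringsAsFactors = FALSE)
  bp <- strsplit(btok, "[-:]")
  bonds <- data.frame(a1 = as.integer(vapply(bp, `[`, "", 1L)),
                      a2 = as.integer(vapply(bp, `[`, "", 2L)),
                      code = vapply(bp, `[`, "", 3L), stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds, pattern = pattern,
                 kind = kind, is_model = is_model),
            class = "csfp_fragment")
}

# ---- matching ----------------------------------------------------------------

# Precomputed matching target. Built from a molecule or from a fragment (the
# latter is how substructure closure between library fragments is computed).
# Atom ids are pre-indexed by element/aromaticity key and bond-node ids by
# bond code, so per-query compatibility domains are cheap lookups.
match_target <- function(x) {
  if (inherits(x, "csfp_mol")) {
    deg <- tabulate(c(x$bonds$a1, x$bonds$a2), nbins = nrow(x$atoms))
    atoms <- data.frame(elem = x$atoms$elem, arom = x$atoms$arom,
                        hyb = x$atoms$hyb, deg = deg,
                        attach = FALSE, stringsAsFactors = FALSE)
    bonds <- data.frame(a1 = x$bonds$a1, a2 = x$bonds$a2,
                        code = bond_code(x$bonds$order, x$bonds$arom),
                        stringsAsFactors = FALSE)
  } else if (inherits(x, "csfp_fragment")) {
    atoms <- x$atoms
    bonds <- x$bonds
  } else stop("unsupported target")
  if (nrow(bonds) == 0L) return(NULL)
  na <- nrow(atoms)
  akey <- paste0(atoms$elem, ifelse(!is.na(atoms$arom) & atoms$arom, "a", ""))
  akey[atoms$attach] <- "*"
  list(g = frag_bipartite(na, bonds),
       na = na, nb = nrow(bonds), atoms = atoms, bonds = bonds,
       hyb = atoms$hyb, deg = atoms$deg,
       by_akey = split(seq_len(na), akey),
       by_code = lapply(split(seq_len(nrow(bonds)), bonds$code),
                        function(ix) ix + na))
}

match_query <- function(frag) {
  a <- frag$atoms
  list(g = frag_bipartite(nrow(a), frag$bonds),
       na = nrow(a), nb = nrow(frag$bonds),
       akey = paste0(a$elem, ifelse(!is.na(a$arom) & a$arom, "a", "")),
       hyb = a$hyb, deg = a$deg, attach = a$attach,
       bcode = frag$bonds$code)
}

# TRUE if the query fragment occurs as a substructure of the target
# (non-induced monomorphism under all atom/bond constraints).
match_substructure <- function(query, target) {
  if (is.null(target)) return(FALSE)
  if (query$na > target$na || query$nb > target$nb) return(FALSE)
  doms <- vector("list", query$na + query$nb)
  for (i in seq_len(query$na)) {
    if (query$attach[i]) {
      d <- seq_len(target$na)
    } else {
      d <- target$by_akey[[query$akey[i]]]
      if (is.null(d)) return(FALSE)
      if (!is.na(query$hyb[i])) d <- d[!is.na(target$hyb[d]) &
                                         target$hyb[d] == query$hyb[i]]
      if (!is.na(query$deg[i])) d <- d[!is.na(target$deg[d]) &
                                         target$deg[d] == query$deg[i]]
      if (length(d) == 0L) return(FALSE)
    }
    doms[[i]] <- d
  }
  for (j in seq_len(query$nb)) {
    d <- target$by_code[[query$bcode[j]]]
    if (is.null(d)) return(FALSE)
    doms[[query$na + j]] <- d
  }
  igraph::subgraph_isomorphic(query$g, target$g, method = "lad",
                              induced = FALSE, domains = doms)
}

# Fast pre-screen data: counts of atom types (plus hybridization- and
# degree-refined counts where the pattern constrains them) and bond codes.
# For a target all constraint-refined keys are concrete, so a pattern profile
# is component-wise <= the target profile whenever a match is possible.
screen_profile <- function(atoms, bonds) {
  real <- !atoms$attach
  a <- atoms[real, , drop = FALSE]
  ar <- ifelse(!is.na(a$arom) & a$arom, "a", "")
  akeys <- paste0(a$elem, ar)
  hsel <- !is.na(a$hyb)
  hkeys <- if (any(hsel)) paste0("h", a$elem[hsel], ar[hsel], a$hyb[hsel])
           else character(0)
  dsel <- !is.na(a$deg)
  dkeys <- if (any(dsel)) paste0("d", a$elem[dsel], ar[dsel], a$deg[dsel])
           else character(0)
  # bond keys refined by endpoint types; bonds to an attachment wildcard
  # cannot be constrained and fall back to a bare code key
  ak_all <- paste0(atoms$elem,
                   ifelse(!is.na(atoms$arom) & atoms$arom, "a", ""))
  ak_all[atoms$attach] <- "*"
  e1 <- ak_all[bonds$a1]; e2 <- ak_all[bonds$a2]
  wild <- e1 == "*" | e2 == "*"
  refined <- if (any(!wild))
    paste0("b", bonds$code[!wild], ":",
           pmin(e1[!wild], e2[!wild]), pmax(e1[!wild], e2[!wild]))
  else character(0)
  c(table(akeys), table(hkeys), table(dkeys),
    table(paste0("b", bonds$code)), table(refined))
}

screen_pass <- function(query_prof, target_prof) {
  v <- target_prof[names(query_prof)]
  v[is.na(v)] <- 0
  all(query_prof <= v)
}
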
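# Independent brute-force substructure matcher and fingerprint oracle.
# Deliberately avoids the package's matching machinery (igraph/LAD, profile
# pre-screens): plain recursive backtracking over atom assignments, with the
# closure expansion recomputed fragment-by-fragment.

brute_target_mol <- function(mol) {
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = nrow(mol$atoms))
  list(atoms = data.frame(elem = mol$atoms$elem, arom = mol$atoms$arom,
                          hyb = mol$atoms$hyb, deg = deg, attach = FALSE,
                          stringsAsFactors = FALSE),
       bonds = data.frame(a1 = mol$bonds$a1, a2 = mol$bonds$a2,
                          code = ifelse(mol$bonds$arom, "ar",
                                        as.character(mol$bonds$order)),
                          stringsAsFactors = FALSE))
}

brute_target_frag <- function(frag) list(atoms = frag$atoms, bonds = frag$bonds)

brute_match <- function(frag, target) {
  pa <- frag$atoms; pb <- frag$bonds
  ta <- target$atoms; tb <- target$bonds
  np <- nrow(pa); nt <- nrow(ta)
  if (np > nt) return(FALSE)
  pc <- matrix("", np, np)
  for (r in seq_len(nrow(pb))) {
    pc[pb$a1[r], pb$a2[r]] <- pb$code[r]
    pc[pb$a2[r], pb$a1[r]] <- pb$code[r]
  }
  tc <- matrix("", nt, nt)
  for (r in seq_len(nrow(tb))) {
    tc[tb$a1[r], tb$a2[r]] <- tb$code[r]
    tc[tb$a2[r], tb$a1[r]] <- tb$code[r]
  }
  # BFS order so every atom after the first has an already-assigned neighbor
  ord <- 1L; seen <- c(TRUE, rep(FALSE, np - 1L))
  while (length(ord) < np) {
    nxt <- which(!seen & apply(pc[, ord, drop = FALSE] != "", 1, any))
    if (length(nxt) == 0L) nxt <- which(!seen)[1]
    ord <- c(ord, nxt[1]); seen[nxt[1]] <- TRUE
  }
  compat <- function(i, t) {
    if (pa$attach[i]) return(TRUE)
    if (isTRUE(ta$attach[t])) return(FALSE)
    if (pa$elem[i] != ta$elem[t]) return(FALSE)
    if (is.na(ta$arom[t]) || pa$arom[i] != ta$arom[t]) return(FALSE)
    if (!is.na(pa$hyb[i]) &&
        (is.na(ta$hyb[t]) || pa$hyb[i] != ta$hyb[t])) return(FALSE)
    if (!is.na(pa$deg[i]) &&
        (is.na(ta$deg[t]) || pa$deg[i] != ta$deg[t])) return(FALSE)
    TRUE
  }
  assign <- rep(NA_integer_, np); used <- rep(FALSE, nt)
  rec <- function(k) {
    if (k > np) return(TRUE)
    i <- ord[k]
    for (t in seq_len(nt)) {
      if (used[t] || !compat(i, t)) next
      ok <- TRUE
      for (j in ord[seq_len(k - 1L)]) {
        code <- pc[i, j]
        if (code != "" && tc[assign[j], t] != code) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[i] <<- t; used[t] <<- TRUE
      if (rec(k + 1L)) return(TRUE)
      assign[i] <<- NA_integer_; used[t] <<- FALSE
    }
    FALSE
  }
  rec(1L)
}

# brute-force CSFP bits: every fragment tested directly against the molecule,
# every closure pair tested independently against the matched fragment
brute_csfp_bits <- function(mol, lib) {
  tgt <- brute_target_mol(mol)
  direct <- which(vapply(lib$fragments, function(f) brute_match(f, tgt), NA))
  bits <- direct
  for (i in direct) {
    cont <- brute_target_frag(lib$fragments[[i]])
    for (j in seq_len(lib$L)) {
      if (j == i) next
      pair_ok <- (lib$kind[i] == "fused" && lib$kind[j] == "single") ||
        (lib$kind[i] == "substituent" && lib$kind[j] == "substituent")
      if (pair_ok && brute_match(lib$fragments[[j]], cont))
        bits <- c(bits, j)
    }
  }
  sort(unique(bits))
}

# library for the worked closure example: naphthalene fused ring + its
# six-ring decomposition fragment, and the propoxy/ethyl/methyl substituent
# chain (propoxy contains exactly two recorded substituents)
closure_example <- function() cached("closure_example", {
  mol <- standardize("CCCOc1ccc2ccccc2c1", ids = "prx")
  subs <- harvest_substituents(mol)
  n_real <- vapply(subs$pattern, function(p)
    sum(!csfpr:::fragment_from_pattern(p, "substituent")$atoms$attach), 1L)
  subs <- subs[n_real %in% c(4L, 2L, 1L), ]        # propoxy, ethyl, methyl
  fused <- extract_ring_systems(mol[[1]])[[1]]
  single <- decompose_fused(fused)[[1]]
  lib <- assemble_library(
    data.frame(pattern = single$pattern, kind = "single",
               is_model = single$is_model, frequency = 1L),
    data.frame(pattern = fused$pattern, kind = "fused",
               is_model = FALSE, frequency = 1L),
    subs, n_single = 1L, n_fused = 1L, n_subs = 3L)
  list(mol = mol[[1]], lib = lib)
})
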
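# CSFP assembly and computation.
#
# The fingerprint is keyed: every bit position corresponds 1:1 to one recorded
# fragment. Bits are laid out single rings first, then fused rings, then
# substituents, frequency-ranked within each category. Substructure closure is
# a property of the recorded library: a fused ring implies the bits of the
# recorded single rings it contains, and a substituent implies the bits of
# recorded substituents contained within it.

#' Assemble a core-substituent fingerprint library
#'
#' Selects the most frequent fragments per category ([select_top()]
#' semantics), assigns bit positions in category order (single rings, fused
#' rings, substituents) and precomputes the substructure-closure map by
#' pairwise matching: fused ring -> contained library single rings, and
#' substituent -> contained library substituents. With default quotas the
#' library has 1000 bit positions, half rings and half substituents.
#'
#' @param rings_single,rings_fused ring catalogs from [build_ring_catalog()]
#'   (`pattern`, `is_model`, `frequency`).
#' @param substituents substituent catalog from [harvest_substituents()].
#' @param n_single,n_fused,n_subs category quotas (250/250/500).
#' @param fused_to_fused also close fused rings over smaller contained fused
#'   rings (off by default; the published design closes fused over singles).
#' @return a `csfp_library`.
#' @export
assemble_library <- function(rings_single, rings_fused, substituents,
                             n_single = 250L, n_fused = 250L, n_subs = 500L,
                             fused_to_fused = FALSE) {
  if (nrow(rings_single) == 0L || nrow(rings_fused) == 0L ||
      nrow(substituents) == 0L)
    stop("empty fragment category: library needs single rings, fused rings and substituents")
  s1 <- select_top(rings_single, n_single)
  s2 <- select_top(rings_fused, n_fused)
  s3 <- select_top(substituents, n_subs)
  frags <- c(
    lapply(seq_len(nrow(s1)), function(i)
      fragment_from_pattern(s1$pattern[i], "single",
                            isTRUE(s1$is_model[i]))),
    lapply(seq_len(nrow(s2)), function(i)
      fragment_from_pattern(s2$pattern[i], "fused",
                            isTRUE(s2$is_model[i]))),
    lapply(seq_len(nrow(s3)), function(i)
      fragment_from_pattern(s3$pattern[i], "substituent")))
  L <- length(frags)
  kind <- vapply(frags, `[[`, "", "kind")
  freq <- c(s1$frequency, s2$frequency, s3$frequency)
  # closure: for each bit, the set of additional bits it implies
  cache <- lib_match_cache(frags)
  targets <- lapply(frags, match_target)
  tprofs <- lapply(frags, function(f) screen_profile(f$atoms, f$bonds))
  closure <- vector("list", L)
  idx_single <- which(kind == "single")
  idx_fused <- which(kind == "fused")
  idx_sub <- which(kind == "substituent")
  contains <- function(container, members) {
    cand <- intersect(cache_candidates(cache, tprofs[[container]]), members)
    cand <- setdiff(cand, container)
    cand[vapply(cand, function(m)
      match_substructure(cache$queries[[m]], targets[[container]]), NA)]
  }
  for (i in idx_fused)
    closure[[i]] <- contains(i, c(idx_single,
                                  if (fused_to_fused) idx_fused))
  for (i in idx_sub)
    closure[[i]] <- contains(i, idx_sub)
  for (i in idx_single) closure[[i]] <- integer()
  structure(list(
    fragments = frags,
    pattern = vapply(frags, `[[`, "", "pattern"),
    kind = kind,
    is_model = vapply(frags, `[[`, NA, "is_model"),
    frequency = as.integer(freq),
    closure = closure,
    n_single = nrow(s1), n_fused = nrow(s2), n_subs = nrow(s3),
    L = L,
    meta = list(requested = c(n_single = n_single, n_fused = n_fused,
                              n_subs = n_subs),
                fused_to_fused = fused_to_fused)),
    class = "csfp_library")
}

#' @export
print.csfp_library <- function(x, ...) {
  cat("<csfp_library> ", x$L, " bits: ", x$n_single, " single rings, ",
      x$n_fused, " fused rings, ", x$n_subs, " substituents; ",
      sum(lengths(x$closure)), " closure edges\n", sep = "")
  invisible(x)
}

# Vectorized pre-screen: fragment count-profile matrix over a fixed key
# space, so candidate fragments for a molecule fall out of one matrix
# comparison instead of per-fragment checks.
lib_match_cache <- function(fragments) {
  profs <- lapply(fragments, function(f) screen_profile(f$atoms, f$bonds))
  keys <- sort(unique(unlist(lapply(profs, names))))
  Fm <- matrix(0L, length(fragments), length(keys),
               dimnames = list(NULL, keys))
  for (i in seq_along(profs)) Fm[i, names(profs[[i]])] <- profs[[i]]
  list(keys = keys, Fm = Fm,
       queries = lapply(fragments, match_query))
}

cache_candidates <- function(cache, tgt_prof) {
  tv <- tgt_prof[cache$keys]
  tv[is.na(tv)] <- 0L
  which(rowSums(cache$Fm > rep(tv, each = nrow(cache$Fm))) == 0L)
}

# match one prepared molecule target against the library; returns list(direct,
# bits) of integer bit positions
.csfp_match_bits <- function(tgt, tgt_prof, lib, cache) {
  direct <- integer()
  for (i in cache_candidates(cache, tgt_prof)) {
    if (match_substructure(cache$queries[[i]], tgt)) direct <- c(direct, i)
  }
  bits <- sort(unique(c(direct, unlist(lib$closure[direct]))))
  list(direct = direct, bits = bits)
}

#' Compute the CSFP of a molecule
#'
#' Sets the bit of every library fragment matching the molecule as a
#' substructure, plus all closure bits those fragments imply. Bits are binary;
#' a molecule matching no fragment yields the all-zero vector.
#'
#' @param mol a `csfp_mol`.
#' @param lib a `csfp_library`.
#' @return a `csfp_fp`: logical `bits` of length `lib$L` plus a `provenance`
#'   data frame (bit, fragment pattern, direct or closure).
#' @export
compute_csfp <- function(mol, lib) {
  stopifnot(inherits(mol, "csfp_mol"), inherits(lib, "csfp_library"))
  tgt <- match_target(mol)
  cache <- lib_match_cache(lib$fragments)
  m <- if (is.null(tgt)) list(direct = integer(), bits = integer()) else
    .csfp_match_bits(tgt, screen_profile(tgt$atoms, tgt$bonds), lib, cache)
  bits <- rep(FALSE, lib$L)
  bits[m$bits] <- TRUE
  prov <- data.frame(bit = m$bits,
                     pattern = lib$pattern[m$bits],
                     via = ifelse(m$bits %in% m$direct, "direct", "closure"),
                     stringsAsFactors = FALSE)
  structure(list(bits = bits, provenance = prov, L = lib$L), class = "csfp_fp")
}

#' @export
print.csfp_fp <- function(x, ...) {
  cat("<csfp_fp> ", sum(x$bits), "/", x$L, " bits set\n", sep = "")
  invisible(x)
}

#' Compute CSFPs for a molecule set as a bit matrix
#'
#' @param mols a `csfp_molset`.
#' @param lib a `csfp_library`.
#' @param verbose print progress every 200 molecules.
#' @return integer 0/1 matrix, molecules in rows (named by id), `lib$L`
#'   columns.
#' @export
compute_csfp_matrix <- function(mols, lib, verbose = FALSE) {
  cache <- lib_match_cache(lib$fragments)
  out <- matrix(0L, nrow = length(mols), ncol = lib$L,
                dimnames = list(vapply(mols, `[[`, "", "id"), NULL))
  for (r in seq_along(mols)) {
    tgt <- match_target(mols[[r]])
    if (is.null(tgt)) next
    m <- .csfp_match_bits(tgt, screen_profile(tgt$atoms, tgt$bonds), lib, cache)
    out[r, m$bits] <- 1L
    if (verbose && r %% 200 == 0) message("  fingerprinted ", r, "/", length(mols))
  }
  out
}

# ---- similarity and summaries ------------------------------------------------

fp_bits <- function(x) {
  if (inherits(x, "csfp_fp")) as.logical(x$bits) else as.logical(x)
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero.
#'
#' @param a,b binary vectors (`csfp_fp` or logical/0-1 vectors) of equal
#'   length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- fp_bits(a); b <- fp_bits(b)
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto matrix between two fingerprint matrices
#'
#' Rows are molecules. Rows with no bits set have similarity 0 to everything.
#'
#' @param A,B 0/1 matrices with the same number of columns.
#' @return `nrow(A)` x `nrow(B)` similarity matrix.
#' @export
tanimoto_matrix <- function(A, B) {
  A <- as.matrix(A) * 1; B <- as.matrix(B) * 1
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  M <- A %*% t(B)
  denom <- outer(rowSums(A), rowSums(B), "+") - M
  K <- ifelse(denom == 0, 0, M / denom)
  dimnames(K) <- list(rownames(A), rownames(B))
  K
}

#' Feature count and bit density of a fingerprint
#'
#' @param v a `csfp_fp` or binary vector/matrix (matrix: per-row counts).
#' @return `feature_count`: number of bits set; `bit_density`: percentage of
#'   bits set.
#' @export
feature_count <- function(v) {
  if (is.matrix(v)) return(rowSums(v != 0))
  sum(fp_bits(v))
}

#' @rdname feature_count
#' @export
bit_density <- function(v) {
  if (is.matrix(v)) return(100 * rowSums(v != 0) / ncol(v))
  b <- fp_bits(v)
  100 * sum(b) / length(b)
}

# ---- comparator fingerprints (Open Babel) -----------------------------------

comparator_fp <- function(mols, name) {
  smi <- vapply(mols, `[[`, "", "smiles")
  ids <- vapply(mols, `[[`, "", "id")
  sdf <- ChemmineR::smiles2sdf(setNames(smi, ids))
  fp <- ChemmineR::fingerprintOB(sdf, name)
  m <- fp@fpma
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' MACCS (166 keys) and folded ECFP4 comparator fingerprints
#'
#' Computed with Open Babel through ChemmineR. MACCS keys 1-166 are extracted
#' from Open Babel's container; the ECFP4 output is folded by OR to `nbits`
#' positions (1024 by default).
#'
#' @param mols a `csfp_molset`.
#' @param nbits folded ECFP4 width.
#' @return 0/1 matrix, molecules in rows.
#' @export
maccs_fp <- function(mols) {
  m <- comparator_fp(mols, "MACCS")
  m[, seq_len(min(166L, ncol(m))), drop = FALSE]
}

#' @rdname maccs_fp
#' @export
ecfp4_fp <- function(mols, nbits = 1024L) {
  m <- comparator_fp(mols, "ECFP4")
  stopifnot(ncol(m) %% nbits == 0)
  folds <- ncol(m) / nbits
  out <- matrix(0L, nrow(m), nbits, dimnames = list(rownames(m), NULL))
  for (f in seq_len(folds))
    out <- out | m[, ((f - 1) * nbits + 1):(f * nbits), drop = FALSE]
  out * 1L
}

# ---- serialization -----------------------------------------------------------

#' Write / read a fingerprint library as JSON
#'
#' The JSON holds patterns, categories, frequencies, closure edges and
#' assembly metadata; fragments are rebuilt from their pattern strings on
#' read.
#'
#' @param lib a `csfp_library`.
#' @param path JSON file path.
#' @export
write_library <- function(lib, path) {
  obj <- list(pattern = lib$pattern, kind = lib$kind, is_model = lib$is_model,
              frequency = lib$frequency,
              closure = lapply(lib$closure, as.integer),
              n_single = lib$n_single, n_fused = lib$n_fused,
              n_subs = lib$n_subs, meta = lib$meta,
              version = as.character(utils::packageVersion("csfpr")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  frags <- lapply(seq_along(obj$pattern), function(i)
    fragment_from_pattern(obj$pattern[i], obj$kind[i], obj$is_model[i]))
  closure <- lapply(obj$closure, function(x) as.integer(unlist(x)))
  structure(list(fragments = frags, pattern = obj$pattern, kind = obj$kind,
                 is_model = obj$is_model, frequency = as.integer(obj$frequency),
                 closure = closure, n_single = obj$n_single,
                 n_fused = obj$n_fused, n_subs = obj$n_subs,
                 L = length(frags), meta = obj$meta),
            class = "csfp_library")
}

#' Write fingerprints to CSV
#'
#' Dense binary CSV: one row per molecule (`id` column followed by `b1..bL`).
#'
#' @param fpm 0/1 fingerprint matrix with row names.
#' @param path output CSV path.
#' @export
write_fingerprints <- function(fpm, path) {
  df <- data.frame(id = rownames(fpm), fpm, check.names = FALSE)
  names(df) <- c("id", paste0("b", seq_len(ncol(fpm))))
  data.table::fwrite(df, path)
  invisible(path)
}
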
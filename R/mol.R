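#' @import methods
#' @importFrom stats median quantile rbinom runif setNames wilcox.test predict
#' @importFrom utils head combn modifyList packageVersion
NULL

# ---- Open Babel plumbing -----------------------------------------------------

ob_options <- function(...) {
  names <- c(...)
  if (length(names) == 0L) return(data.frame(names = character(), args = character()))
  data.frame(names = names, args = rep("", length(names)), stringsAsFactors = FALSE)
}

# Batch SMILES -> canonical SMILES through Open Babel, alignment-safe via titles.
# Returns character vector aligned with input; unparseable entries raise an error
# naming the offending SMILES.
ob_canonical <- function(smiles, strip_salts = FALSE, neutralize = FALSE,
                         on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(!nzchar(smiles))) stop("empty SMILES string at position ",
                                 which(!nzchar(smiles))[1])
  titles <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, titles), collapse = "\n")
  opts <- c(if (strip_salts) "r", if (neutralize) "neutralize")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"),
                                   options = ob_options(opts))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) trimws(p[min(2L, length(p))]), "")
  smi <- vapply(parts, `[`, "", 1L)
  res <- setNames(rep(NA_character_, length(smiles)), titles)
  res[got[got %in% titles]] <- smi[got %in% titles]
  if (anyNA(res) && on_error == "stop") {
    bad <- smiles[is.na(res)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  unname(res)
}

# ---- molecule records --------------------------------------------------------

#' Standardize SMILES into molecule records
#'
#' Canonicalizes SMILES through Open Babel: aromaticity is perceived, salts and
#' solvents are stripped to the largest organic component, and +1/-1 charges are
#' neutralized where toolkit-standard. Each record carries the canonical SMILES
#' and a parsed molecular graph used by all downstream fragmentation and
#' matching operations.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers (defaults to `M1..Mn`).
#' @param activity_class optional class labels, recycled.
#' @param strip_salts keep only the largest connected component.
#' @param neutralize neutralize +1/-1 charges.
#' @return a list of `csfp_mol` records (id, canonical `smiles`, atom and bond
#'   tables); of class `csfp_molset`.
#' @examples
#' m <- standardize("C1=CC=CC=C1")[[1]]
#' m$smiles                     # "c1ccccc1"
#' @export
standardize <- function(smiles, ids = NULL, activity_class = NULL,
                        strip_salts = TRUE, neutralize = TRUE) {
  stopifnot(length(smiles) >= 1L)
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  can <- ob_canonical(smiles, strip_salts = strip_salts, neutralize = neutralize)
  mols <- parse_canonical(can, ids)
  if (!is.null(activity_class)) {
    activity_class <- rep_len(activity_class, length(mols))
    for (i in seq_along(mols)) mols[[i]]$activity_class <- activity_class[[i]]
  }
  structure(mols, class = "csfp_molset")
}

#' @export
print.csfp_molset <- function(x, ...) {
  cat("<csfp_molset> of", length(x), "molecules\n")
  n <- min(5L, length(x))
  for (i in seq_len(n)) cat("  ", x[[i]]$id, " ", x[[i]]$smiles, "\n", sep = "")
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.csfp_molset` <- function(x, i) structure(unclass(x)[i], class = "csfp_molset")

# Parse canonical SMILES into graph records. Two aligned Open Babel conversions:
# MOL2 supplies aromaticity (SYBYL 'ar' bonds/types), SDF supplies kekulized
# bond orders and formal charges (M  CHG lines). Atom order is preserved by OB
# across both outputs for identical input.
parse_canonical <- function(can, ids) {
  titles <- paste0("m", seq_along(can))
  src <- paste0(paste(can, titles), collapse = "\n")
  mol2 <- ChemmineOB::convertFormat("SMI", "MOL2", paste0(src, "\n"))
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(src, "\n"))
  m2 <- parse_mol2_blocks(mol2)
  sd <- parse_sdf_blocks(sdf)
  stopifnot(identical(names(m2), titles), identical(names(sd), titles))
  mols <- vector("list", length(can))
  for (i in seq_along(can)) {
    a2 <- m2[[i]]; as <- sd[[i]]
    if (nrow(a2$atoms) != nrow(as$atoms) ||
        !identical(a2$atoms$elem, as$atoms$elem))
      stop("internal: MOL2/SDF atom tables disagree for ", ids[i])
    bonds <- as$bonds
    # aromatic flag per bond from MOL2 (same atom indices, possibly reordered rows)
    key <- function(b) paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    arom_keys <- key(a2$bonds)[a2$bonds$ar]
    bonds$arom <- key(bonds) %in% arom_keys
    natom <- nrow(a2$atoms)
    arom_atom <- rep(FALSE, natom)
    arom_atom[c(bonds$a1[bonds$arom], bonds$a2[bonds$arom])] <- TRUE
    arom_atom <- arom_atom | a2$atoms$ar
    # hybridization from kekule orders (aromatic forced sp2)
    dmax <- rep(1L, natom); ndouble <- rep(0L, natom)
    for (j in seq_len(nrow(bonds))) {
      o <- bonds$order[j]
      for (a in c(bonds$a1[j], bonds$a2[j])) {
        dmax[a] <- max(dmax[a], o)
        if (o == 2L) ndouble[a] <- ndouble[a] + 1L
      }
    }
    hyb <- ifelse(arom_atom | dmax == 2L, 2L, 3L)
    hyb[dmax == 3L | ndouble >= 2L] <- 1L
    atoms <- data.frame(elem = a2$atoms$elem, arom = arom_atom, hyb = hyb,
                        charge = as$atoms$charge, stringsAsFactors = FALSE)
    mols[[i]] <- structure(list(id = ids[i], smiles = can[i], atoms = atoms,
                                bonds = bonds[, c("a1", "a2", "order", "arom")],
                                activity_class = NULL),
                          class = "csfp_mol")
  }
  names(mols) <- ids
  mols
}

#' @export
print.csfp_mol <- function(x, ...) {
  cat("<csfp_mol> ", x$id, ": ", x$smiles, " (", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

parse_mol2_blocks <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  out <- list()
  for (s in seq_along(starts)) {
    i0 <- starts[s]
    i1 <- if (s < length(starts)) starts[s + 1] - 1L else length(lines)
    blk <- lines[i0:i1]
    title <- trimws(blk[2])
    ia <- which(blk == "@<TRIPOS>ATOM")
    ib <- which(blk == "@<TRIPOS>BOND")
    counts <- as.integer(strsplit(trimws(blk[3]), "\\s+")[[1]][1:2])
    atoms_raw <- blk[(ia + 1):(ia + counts[1])]
    af <- strsplit(trimws(atoms_raw), "\\s+")
    type <- vapply(af, `[`, "", 6L)
    elem <- sub("\\..*$", "", type)
    ar <- grepl("\\.ar$", type)
    bonds <- if (counts[2] > 0) {
      braw <- blk[(ib + 1):(ib + counts[2])]
      bf <- strsplit(trimws(braw), "\\s+")
      data.frame(a1 = as.integer(vapply(bf, `[`, "", 2L)),
                 a2 = as.integer(vapply(bf, `[`, "", 3L)),
                 ar = vapply(bf, `[`, "", 4L) == "ar",
                 stringsAsFactors = FALSE)
    } else data.frame(a1 = integer(), a2 = integer(), ar = logical())
    out[[title]] <- list(atoms = data.frame(elem = elem, ar = ar,
                                            stringsAsFactors = FALSE),
                         bonds = bonds)
  }
  out
}

parse_sdf_blocks <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  out <- list(); start <- 1L
  for (e in ends) {
    blk <- lines[start:(e - 1L)]
    start <- e + 1L
    title <- trimws(blk[1])
    counts <- blk[4]
    na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
    arows <- blk[5:(4 + na)]
    elem <- trimws(substr(arows, 32, 34))
    charge <- rep(0L, na)
    bonds <- if (nb > 0) {
      brows <- blk[(5 + na):(4 + na + nb)]
      data.frame(a1 = as.integer(substr(brows, 1, 3)),
                 a2 = as.integer(substr(brows, 4, 6)),
                 order = as.integer(substr(brows, 7, 9)))
    } else data.frame(a1 = integer(), a2 = integer(), order = integer())
    for (ln in grep("^M  CHG", blk, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) charge[f[2 * k]] <- f[2 * k + 1]
    }
    out[[title]] <- list(atoms = data.frame(elem = elem, charge = charge,
                                            stringsAsFactors = FALSE),
                         bonds = bonds)
  }
  out
}

# ---- molblock export (subgraph -> canonical SMILES) -------------------------

# V2000 molblock for an atom subset of a molecule (induced bonds, kekule
# orders); open valences become implicit hydrogens on re-perception, which is
# how cores are generalized by hydrogen-capping.
molblock <- function(mol, atom_idx, title = "frag") {
  atom_idx <- sort(atom_idx)
  remap <- match(seq_len(nrow(mol$atoms)), atom_idx)
  b <- mol$bonds[mol$bonds$a1 %in% atom_idx & mol$bonds$a2 %in% atom_idx, , drop = FALSE]
  na <- length(atom_idx); nb <- nrow(b)
  hdr <- c(title, "  csfpr", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, mol$atoms$elem[atom_idx])
  bt <- if (nb > 0) sprintf("%3d%3d%3d  0", remap[b$a1], remap[b$a2], b$order) else character()
  chg <- which(mol$atoms$charge[atom_idx] != 0L)
  ch <- if (length(chg)) {
    vapply(chg, function(k) sprintf("M  CHG  1 %3d %3d", k,
                                    mol$atoms$charge[atom_idx][k]), "")
  } else character()
  c(hdr, at, bt, ch, "M  END", "$$$$")
}

# Canonical SMILES for many atom subsets in one Open Babel call.
# atom_sets: named list of integer vectors (names = output names).
subgraph_smiles <- function(mol, atom_sets) {
  if (length(atom_sets) == 0L) return(character())
  if (is.null(names(atom_sets))) names(atom_sets) <- paste0("f", seq_along(atom_sets))
  blocks <- unlist(lapply(names(atom_sets), function(nm)
    molblock(mol, atom_sets[[nm]], title = nm)))
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- setNames(vapply(parts, `[`, "", 1L),
                  vapply(parts, function(p) trimws(p[min(2L, length(p))]), ""))
  res[names(atom_sets)]
}

# ---- file I/O ----------------------------------------------------------------

#' Read molecules from .smi or delimited files
#'
#' `.smi` files hold one `SMILES [id]` per line; CSV/TSV files must have
#' `smiles` and (optionally) `id` and `activity_class` columns. Gzip is handled
#' transparently.
#'
#' @param path input file.
#' @param standardize_input standardize/canonicalize on read.
#' @return a `csfp_molset`.
#' @export
read_molecules <- function(path, standardize_input = TRUE) {
  ext <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.smi$", ext)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    smiles <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
    if (anyNA(ids)) ids <- NULL
    df <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
    if (!is.null(ids)) df$id <- ids
  } else {
    df <- as.data.frame(data.table::fread(path))
    if (!"smiles" %in% names(df)) stop("no 'smiles' column in ", path)
  }
  standardize(df$smiles, ids = df[["id"]],
              activity_class = df[["activity_class"]],
              strip_salts = standardize_input, neutralize = standardize_input)
}

#' Write molecules to a .smi or TSV file
#'
#' @param mols a `csfp_molset`.
#' @param path output path (`.smi`, `.csv`, `.tsv`; `.gz` transparent).
#' @export
write_molecules <- function(mols, path) {
  df <- data.frame(id = vapply(mols, `[[`, "", "id"),
                   smiles = vapply(mols, `[[`, "", "smiles"),
                   stringsAsFactors = FALSE)
  cls <- lapply(mols, `[[`, "activity_class")
  if (any(!vapply(cls, is.null, TRUE)))
    df$activity_class <- vapply(cls, function(x) if (is.null(x)) NA_character_ else x, "")
  if (grepl("\\.smi(\\.gz)?$", tolower(path))) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste(df$smiles, df$id), con)
  } else {
    data.table::fwrite(df, path, sep = if (grepl("\\.tsv", path)) "\t" else ",")
  }
  invisible(path)
}
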
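# Synthetic fixture generator.
#
# Emulates the structure of medicinal-chemistry compound collections at desk
# scale: analogue series share a ring-containing core (a fused ring system
# linked to a single ring) and vary R-groups drawn from a large pool at one or
# two substitution sites. Ring and R-group pools are enumerated
# deterministically (heteroatom placements over ring skeletons; element words
# for chains) and deduplicated at the fragment-pattern level, so generated
# collections exercise hundreds of distinct single rings, fused systems and
# substituents. Randomness is confined to sampling from those pools under a
# caller-supplied seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.fixture_cache <- new.env(parent = emptyenv())

# ring assembly from atom tokens: tokens[1] opens the ring, branches attach
# "(...)" after interior tokens, a suffix attaches after ring closure
assemble_ring <- function(tokens, branches = list(), suffix = "") {
  n <- length(tokens)
  out <- paste0(tokens[1], "1")
  for (i in 2:(n - 1)) {
    out <- paste0(out, tokens[i])
    if (!is.null(branches[[as.character(i)]]))
      out <- paste0(out, "(", branches[[as.character(i)]], ")")
  }
  paste0(out, tokens[n], "1", suffix)
}

# saturated ring token variants: heteroatoms at position subsets (never
# position 1, kept attachable)
sat_ring_tokens <- function(size, letters = c("O", "N", "S"), max_het = 3L) {
  out <- list(rep("C", size))
  for (k in seq_len(min(max_het, size - 1L))) {
    pos_sets <- utils::combn(2:size, k, simplify = FALSE)
    assign_sets <- expand.grid(rep(list(letters), k), stringsAsFactors = FALSE)
    for (p in pos_sets) for (r in seq_len(nrow(assign_sets))) {
      t <- rep("C", size)
      t[p] <- unlist(assign_sets[r, ])
      out[[length(out) + 1L]] <- t
    }
  }
  out
}

arom6_tokens <- function(max_n = 4L) {
  out <- list(rep("c", 6))
  for (k in seq_len(min(max_n, 5L))) {
    for (p in utils::combn(2:6, k, simplify = FALSE)) {
      t <- rep("c", 6); t[p] <- "n"
      out[[length(out) + 1L]] <- t
    }
  }
  out
}

arom5_tokens <- function() {
  out <- list()
  for (x in c("o", "s", "[nH]")) for (xp in 2:5) {
    t <- rep("c", 5); t[xp] <- x
    out[[length(out) + 1L]] <- t
    for (np in setdiff(2:5, xp)) {
      t2 <- t; t2[np] <- "n"
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

# fused-ring SMILES variants from hand-built skeletons with substitutable
# positions (position indices refer to entries of the token vector)
fused_ring_smiles <- function() {
  out <- character()
  subst <- function(tokens, positions, letters, max_k) {
    res <- list(tokens)
    for (k in seq_len(min(max_k, length(positions)))) {
      for (p in utils::combn(positions, k, simplify = FALSE)) {
        grid <- expand.grid(rep(list(letters), k), stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grid))) {
          t <- tokens; t[p] <- unlist(grid[r, ])
          res[[length(res) + 1L]] <- t
        }
      }
    }
    vapply(res, paste, "", collapse = "")
  }
  # naphthalene: atoms at tokens 1,3,4,5,7,8,9,10,12,13; fusion = 5,10
  naph <- c("c", "1", "c", "c", "c", "2", "c", "c", "c", "c", "c", "2", "c", "1")
  out <- c(out, subst(naph, c(3, 4, 7, 8, 9, 10, 13), "n", 2L))
  # decalin
  dec <- c("C", "1", "C", "C", "C", "2", "C", "C", "C", "C", "C", "2", "C", "1")
  out <- c(out, subst(dec, c(3, 4, 7, 8, 9, 10, 13), c("O", "N", "S"), 2L))
  # tetralin: benzo + saturated ring
  tet <- c("c", "1", "c", "c", "c", "2", "c", "(", "c", "1", ")", "C", "C", "C", "C", "2")
  out <- c(out, subst(tet, c(3, 4, 9), "n", 1L))
  out <- c(out, subst(tet, c(12, 13, 14, 15), c("O", "N", "S"), 2L))
  # indane
  ind <- c("c", "1", "c", "c", "c", "2", "c", "(", "c", "1", ")", "C", "C", "C", "2")
  out <- c(out, subst(ind, c(12, 13, 14), c("O", "N", "S"), 2L))
  # 6-5 aromatic (indole/benzofuran/benzothiophene-like)
  for (x in c("[nH]", "o", "s")) {
    b65 <- c("c", "1", "c", "c", "c", "2", "c", "(", "c", "1", ")", "c", "c", x, "2")
    out <- c(out, subst(b65, c(3, 4, 12, 13), "n", 1L))
  }
  # spiro[4.5]decane
  spiro <- c("C", "1", "C", "C", "C", "2", "(", "C", "1", ")", "C", "C", "C", "C", "C", "2")
  out <- c(out, subst(spiro, c(3, 4, 11, 12, 13, 14), c("O", "N"), 2L))
  # hydrindane (fused 6-5, saturated)
  hyd <- c("C", "1", "C", "C", "C", "2", "C", "C", "C", "C", "2", "C", "1")
  out <- c(out, subst(hyd, c(3, 4, 7, 8, 9, 12), c("O", "N", "S"), 2L))
  # bicyclo[3.3.0]octane (fused 5-5, saturated)
  p55 <- c("C", "1", "C", "C", "2", "C", "C", "C", "C", "2", "C", "1")
  out <- c(out, subst(p55, c(3, 6, 7, 8, 11), c("O", "N", "S"), 2L))
  # benzosuberane (fused 6-7)
  b67 <- c("c", "1", "c", "c", "c", "2", "c", "(", "c", "1", ")",
           "C", "C", "C", "C", "C", "2")
  out <- c(out, subst(b67, c(12, 13, 14, 15, 16), c("O", "N", "S"), 2L))
  unique(out)
}

# parse candidates, keep those with exactly one ring system of the wanted
# kind, dedupe by fragment pattern; returns data.frame(smiles, pattern)
dedupe_by_pattern <- function(smiles, kind) {
  can <- ob_canonical(smiles, on_error = "na")
  keep <- !is.na(can) & !duplicated(can)
  smiles <- smiles[keep]
  mols <- tryCatch(standardize(smiles, strip_salts = FALSE, neutralize = FALSE),
                   error = function(e) NULL)
  if (is.null(mols)) return(data.frame(smiles = character(), pattern = character()))
  pat <- rep(NA_character_, length(mols))
  nat <- rep(NA_integer_, length(mols))
  for (i in seq_along(mols)) {
    fs <- tryCatch(extract_ring_systems(mols[[i]]), error = function(e) NULL)
    if (is.null(fs) || length(fs) != 1L || fs[[1]]$kind != kind) next
    pat[i] <- fs[[1]]$pattern
    nat[i] <- nrow(mols[[i]]$atoms)
  }
  ok <- !is.na(pat) & !duplicated(pat)
  data.frame(smiles = smiles[ok], pattern = pat[ok], natoms = nat[ok],
             stringsAsFactors = FALSE)
}

#' Deterministic fixture pools of rings and R-groups
#'
#' Enumerates single-ring and fused-ring skeleton variants (heteroatom
#' placements over saturated and aromatic rings and over fused skeletons) and
#' chain-like R-group SMILES snippets, deduplicated at the fragment-pattern
#' level. The pools are the raw material of the fixture generators; they are
#' cached per session.
#'
#' @return list with `single` (token lists), `single_patterns`, `fused`
#'   (data frame smiles/pattern), `rgroups` (character snippets).
#' @export
fixture_pools <- function() {
  if (!is.null(.fixture_cache$pools)) return(.fixture_cache$pools)
  single_tokens <- c(sat_ring_tokens(6), sat_ring_tokens(5, max_het = 2L),
                     sat_ring_tokens(7), sat_ring_tokens(4, max_het = 2L),
                     sat_ring_tokens(8, max_het = 2L), sat_ring_tokens(3, max_het = 1L),
                     arom6_tokens(), arom5_tokens())
  single_smiles <- vapply(single_tokens, function(t) assemble_ring(t), "")
  sing <- dedupe_by_pattern(single_smiles, "single")
  # keep the token lists of the surviving variants, aligned with patterns
  tok_keep <- single_tokens[match(sing$smiles, single_smiles)]
  fused <- dedupe_by_pattern(fused_ring_smiles(), "fused")
  # R-group snippets: element words (attachment at first atom), halogen caps,
  # a few branched/functional specials
  words <- function(len, alphabet) {
    g <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
    apply(g, 1, paste, collapse = "")
  }
  rg <- c(unlist(lapply(1:4, words, alphabet = c("C", "N", "O", "S"))),
          unlist(lapply(5L, words, alphabet = c("C", "N", "O"))),
          paste0(unlist(lapply(1:2, words, alphabet = c("C", "N", "O"))),
                 rep(c("F", "Cl", "Br"), each = 12)),
          "C(F)(F)F", "C#N", "C=C", "C(=O)C", "C(=O)O", "C(=O)N",
          "S(=O)(=O)C", "C(C)C", "C(C)(C)C", "N(C)C", "OC(F)(F)F", "C=CC")
  rg <- unique(rg)
  rg_atoms <- vapply(rg, function(s)
    length(gregexpr("Cl|Br|[CNOSF]", s)[[1]]), 1L, USE.NAMES = FALSE)
  pools <- list(single = tok_keep, single_patterns = sing$pattern,
                single_smiles = sing$smiles, fused = fused,
                rgroups = rg, rg_atoms = rg_atoms)
  .fixture_cache$pools <- pools
  pools
}

# One series-core recipe: a single ring carrying the fused ring system at its
# first attachable site and R-group sites at the remaining ones. Attachable
# sites are interior C/c tokens (branch attachment) plus the ring-closing
# token when it is a carbon (suffix attachment).
series_core_recipe <- function(fused_idx, single_idx, n_sites, pools) {
  tokens <- pools$single[[single_idx]]
  n <- length(tokens)
  interior <- which(tokens %in% c("C", "c"))
  interior <- interior[interior >= 2 & interior <= n - 1]
  avail <- as.list(interior)
  if (tokens[n] %in% c("C", "c")) avail <- c(avail, list("suffix"))
  if (length(avail) < 2L) return(NULL)   # need link site + >= 1 R site
  link <- avail[[1]]
  rsites <- avail[-1]
  rsites <- rsites[seq_len(min(n_sites, length(rsites)))]
  list(fused_smiles = pools$fused$smiles[fused_idx], tokens = tokens,
       link = link, sites = rsites,
       core_atoms = pools$fused$natoms[fused_idx] + length(tokens))
}

# sample R-groups whose combined heavy-atom count respects the 2:1
# core-to-substituent ratio, so the shared series core is recoverable by
# systematic fragmentation
sample_rgroups <- function(n, budget, pools) {
  out <- character(n)
  remaining <- budget
  for (j in seq_len(n)) {
    reserve <- n - j
    ok <- which(pools$rg_atoms <= remaining - reserve)
    if (length(ok) == 0L) ok <- which(pools$rg_atoms == 1L)
    pick <- ok[sample.int(length(ok), 1L)]
    out[j] <- pools$rgroups[pick]
    remaining <- remaining - pools$rg_atoms[pick]
  }
  out
}

series_member_smiles <- function(recipe, rgs) {
  branches <- list(); suffix <- ""
  assign_site <- function(site, content) {
    if (identical(site, "suffix")) suffix <<- content
    else branches[[as.character(site)]] <<- content
  }
  # renumber the fused system's ring-closure digits so they cannot collide
  # with the open ring digit of the hosting single ring
  assign_site(recipe$link, chartr("12", "89", recipe$fused_smiles))
  for (j in seq_along(recipe$sites)) assign_site(recipe$sites[[j]], rgs[j])
  assemble_ring(recipe$tokens, branches, suffix)
}

#' Generate synthetic analogue series
#'
#' Each series shares one ring-containing core (a fused ring system linked to
#' a single ring) and varies R-groups from the fixture pool at one or two
#' substitution sites; members of a series carry its id as `activity_class`.
#' Fused and single rings are cycled through the pools so large collections
#' exercise the full pool diversity. Deterministic for a fixed seed; all
#' generated molecules are unique.
#'
#' @param n_series number of series (>= 1).
#' @param series_size compounds per series (>= 2).
#' @param seed integer seed.
#' @param n_sites substitution sites per series core (1 or 2; default
#'   alternates).
#' @return a `csfp_molset` with ids `S<i>_<j>` and `activity_class = "S<i>"`.
#' @export
generate_fixture_series <- function(n_series, series_size, seed, n_sites = NULL) {
  stopifnot(n_series >= 1L, series_size >= 2L)
  pools <- fixture_pools()
  with_seed(seed, {
    smiles <- character(); ids <- character(); cls <- character()
    for (i in seq_len(n_series)) {
      fi <- ((i - 1L) %% nrow(pools$fused)) + 1L
      si <- ((i - 1L) %% length(pools$single)) + 1L
      ns <- if (is.null(n_sites)) 1L + (i %% 2L) else as.integer(n_sites)
      recipe <- NULL
      for (shift in 0:(length(pools$single) - 1L)) {  # some rings lack sites
        si2 <- ((si - 1L + shift) %% length(pools$single)) + 1L
        recipe <- series_core_recipe(fi, si2, ns, pools)
        if (!is.null(recipe)) break
      }
      if (is.null(recipe)) stop("no usable single-ring skeleton in pool")
      ns_eff <- length(recipe$sites)
      budget <- floor(recipe$core_atoms / 2)
      combos <- list(); tries <- 0L
      while (length(combos) < series_size && tries < 50L * series_size) {
        tries <- tries + 1L
        rgs <- sample_rgroups(max(1L, ns_eff), budget, pools)
        key <- paste(rgs, collapse = "|")
        if (!key %in% names(combos)) combos[[key]] <- rgs
      }
      combos <- combos[seq_len(min(series_size, length(combos)))]
      for (j in seq_along(combos)) {
        smiles <- c(smiles, series_member_smiles(recipe, combos[[j]]))
        ids <- c(ids, paste0("S", i, "_", j))
        cls <- c(cls, paste0("S", i))
      }
    }
    mols <- standardize(smiles, ids = ids, activity_class = cls)
    # canonical-SMILES collisions across series are dropped (kept unique)
    can <- vapply(mols, `[[`, "", "smiles")
    mols[!duplicated(can)]
  })
}

#' Generate random singleton fixture compounds (decoys)
#'
#' Each compound is an independently sampled core (fused system plus single
#' ring) decorated with random R-groups; no two compounds share design.
#' Optionally excludes cores whose ring patterns intersect a given set, which
#' mirrors benchmark protocols that exclude an activity class from the
#' background database.
#'
#' @param n number of compounds.
#' @param seed integer seed.
#' @param exclude_patterns character vector of ring fragment patterns that
#'   must not occur in the sampled cores.
#' @return a `csfp_molset` with ids `D1..Dn`.
#' @export
generate_fixture_compounds <- function(n, seed, exclude_patterns = character()) {
  pools <- fixture_pools()
  ok_f <- !(pools$fused$pattern %in% exclude_patterns)
  ok_s <- !(pools$single_patterns %in% exclude_patterns)
  with_seed(seed, {
    smiles <- character()
    guard <- 0L
    while (length(smiles) < n && guard < 50L * n) {
      guard <- guard + 1L
      fi <- sample(which(ok_f), 1L)
      si <- sample(which(ok_s), 1L)
      ns <- sample(1:2, 1L)
      recipe <- series_core_recipe(fi, si, ns, pools)
      if (is.null(recipe)) next
      rgs <- sample(pools$rgroups, max(1L, length(recipe$sites)))
      smiles <- unique(c(smiles, series_member_smiles(recipe, rgs)))
    }
    standardize(smiles, ids = paste0("D", seq_along(smiles)))
  })
}

#' Generate a synthetic activity-record table
#'
#' Produces ChEMBL-style rows exercising every curation filter: molecular
#' weight, confidence score, relation, assay type, potency cutoff and
#' exclusion flags, plus clean records that survive curation.
#'
#' @param n_clean number of records passing all filters.
#' @param seed integer seed.
#' @return data frame in the [curate_activity_records()] input layout.
#' @export
generate_fixture_activity_table <- function(n_clean = 10L, seed = 1L) {
  pools <- fixture_pools()
  with_seed(seed, {
    mk <- function(i, ...) {
      rec <- list(compound_id = paste0("C", i), smiles = "c1ccccc1CC",
                  target_id = "T1", standard_type = "Ki",
                  standard_relation = "=",
                  standard_value_nM = round(runif(1, 1, 9000), 1),
                  confidence_score = 9L, flags = "",
                  mol_weight_Da = round(runif(1, 200, 600), 1))
      modifyList(rec, list(...))
    }
    clean <- lapply(seq_len(n_clean), function(i)
      mk(i, compound_id = paste0("OK", i)))
    bad <- list(
      mk(101, standard_relation = ">"),
      mk(102, flags = "inconclusive"),
      mk(103, confidence_score = 7L),
      mk(104, standard_value_nM = 50000),
      mk(105, mol_weight_Da = 1450),
      mk(106, standard_type = "EC50"),
      mk(107, flags = "potential transcription error"))
    do.call(rbind, lapply(c(clean, bad), function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  })
}
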
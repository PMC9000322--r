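# Activity-record curation (ChEMBL-style high-confidence data selection).

EXCLUDED_FLAGS <- c("inactive", "not active", "inconclusive",
                    "potential transcription error")

REQUIRED_RECORD_FIELDS <- c("compound_id", "smiles", "target_id",
                            "standard_type", "standard_relation",
                            "standard_value_nM", "confidence_score",
                            "mol_weight_Da")

#' Curate activity records
#'
#' Applies the high-confidence selection filters: molecular weight below
#' `mw_cutoff_Da`, direct target annotation (confidence score 9), exact
#' potency (`standard_relation == "="`) of type Ki/IC50/Kd, potency within the
#' cutoff (at most `potency_cutoff_nM` by default; weaker interactions are
#' disregarded), and none of the exclusion flags ("inactive", "not active",
#' "inconclusive", "potential transcription error"). Anti-target removal and
#' assay-interference filtering attach via hooks. Duplicates per
#' (compound, target) are collapsed to a single record carrying the median
#' potency.
#'
#' @param records data frame with columns `compound_id`, `smiles`,
#'   `target_id`, `standard_type`, `standard_relation`, `standard_value_nM`,
#'   `confidence_score`, `mol_weight_Da` and optional `flags`
#'   (semicolon-separated).
#' @param potency_cutoff_nM potency cutoff in nM (10 uM default).
#' @param mw_cutoff_Da molecular weight cutoff in Da.
#' @param potency_direction `"keep_potent"` keeps values `<=` cutoff (the
#'   conventional reading); `"keep_weak"` keeps values `>=` cutoff.
#' @param anti_targets character vector of target ids to drop (e.g.
#'   pharmaceutical anti-targets such as hERG or serum albumin).
#' @param interference_predicate optional hook `f(records)` returning a
#'   logical vector; rows marked `TRUE` are removed (assay-interference
#'   filters).
#' @return the curated subset, one row per (compound, target).
#' @export
curate_activity_records <- function(records,
                                    potency_cutoff_nM = 10000,
                                    mw_cutoff_Da = 1000,
                                    potency_direction = c("keep_potent", "keep_weak"),
                                    anti_targets = character(),
                                    interference_predicate = NULL) {
  potency_direction <- match.arg(potency_direction)
  stopifnot(potency_cutoff_nM > 0, mw_cutoff_Da > 0)
  miss <- setdiff(REQUIRED_RECORD_FIELDS, names(records))
  if (length(miss) > 0)
    stop("records lack required fields: ", paste(miss, collapse = ", "))
  for (f in REQUIRED_RECORD_FIELDS) {
    bad <- is.na(records[[f]])
    if (any(bad))
      stop("missing ", f, " for record ",
           records$compound_id[which(bad)[1]])
  }
  if (is.null(records$flags)) records$flags <- ""
  flag_hit <- vapply(strsplit(tolower(records$flags), ";"), function(fl)
    any(trimws(fl) %in% EXCLUDED_FLAGS), NA)
  keep <- records$mol_weight_Da < mw_cutoff_Da &
    records$confidence_score == 9L &
    records$standard_relation == "=" &
    records$standard_type %in% c("Ki", "IC50", "Kd") &
    records$standard_value_nM > 0 &
    (if (potency_direction == "keep_potent")
      records$standard_value_nM <= potency_cutoff_nM
     else records$standard_value_nM >= potency_cutoff_nM) &
    !flag_hit &
    !(records$target_id %in% anti_targets)
  out <- records[keep, , drop = FALSE]
  if (!is.null(interference_predicate) && nrow(out) > 0) {
    drop <- interference_predicate(out)
    stopifnot(is.logical(drop), length(drop) == nrow(out))
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) == 0) { rownames(out) <- NULL; return(out) }
  # collapse duplicates per (compound, target): median potency, most potent
  # row retained otherwise
  key <- paste(out$compound_id, out$target_id, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(out)), key), function(ix) {
    ix <- ix[order(out$standard_value_nM[ix])]
    row <- out[ix[1], , drop = FALSE]
    row$standard_value_nM <- median(out$standard_value_nM[ix])
    row
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$compound_id, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
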
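# k-NN similarity-search benchmark protocol.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties credited 1/2.
#'
#' @param pos_scores,neg_scores numeric score vectors (higher = more
#'   active-like).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop("auc_roc() needs non-empty positive and negative score sets")
  r <- rank(c(pos_scores, neg_scores))   # average ranks handle ties as 1/2
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' k-nearest-neighbor similarity score against a reference set
#'
#' Tanimoto similarity to every reference fingerprint; the final score is the
#' maximum for `k = 1` and the mean of the `k` largest values otherwise.
#'
#' @param db_fp binary fingerprint of the database compound.
#' @param ref_fps matrix of reference fingerprints (rows) or list of vectors.
#' @param k number of nearest neighbors (1, 5 or 10 in the protocol).
#' @return final similarity score.
#' @export
knn_score <- function(db_fp, ref_fps, k = 1L) {
  if (is.list(ref_fps)) ref_fps <- do.call(rbind, lapply(ref_fps, fp_bits)) * 1
  if (k < 1 || k > nrow(ref_fps))
    stop("k must be between 1 and the number of reference compounds")
  tcs <- as.numeric(tanimoto_matrix(matrix(fp_bits(db_fp) * 1, nrow = 1), ref_fps))
  if (k == 1L) max(tcs) else mean(sort(tcs, decreasing = TRUE)[seq_len(k)])
}

# vectorized trial scoring: db rows against refs
knn_scores <- function(db_mat, ref_mat, k) {
  K <- tanimoto_matrix(db_mat, ref_mat)
  if (k == 1L) apply(K, 1, max)
  else apply(K, 1, function(x) mean(sort(x, decreasing = TRUE)[seq_len(k)]))
}

#' Run similarity-search trials for one activity class
#'
#' Per trial, `n_sample` actives are drawn; `n_ref` of them serve as
#' references and the rest are potential hits spiked into the background
#' database. Every database compound receives the k-NN Tanimoto score against
#' the references and the trial is summarized as the AUC ROC of hits versus
#' background. Trials are independent and fully reproducible: per-trial seeds
#' are derived from the master seed by trial index.
#'
#' @param active_fps fingerprint matrix of the activity class (rows named by
#'   id).
#' @param background_fps fingerprint matrix of the background database
#'   (disjoint from the actives).
#' @param k nearest-neighbor parameter (1, 5 or 10).
#' @param n_trials number of independent trials (20 in the protocol).
#' @param n_sample actives sampled per trial (100 in the protocol).
#' @param n_ref references among the sampled actives (10 in the protocol).
#' @param seed master seed.
#' @return list with `trials` (data frame: trial, seed, auc) and `mean_auc`.
#' @export
run_trials <- function(active_fps, background_fps, k = 1L, n_trials = 20L,
                       n_sample = 100L, n_ref = 10L, seed = 1L) {
  if (nrow(active_fps) < n_sample)
    stop("insufficient actives: ", nrow(active_fps), " < n_sample = ", n_sample)
  if (any(rownames(active_fps) %in% rownames(background_fps)))
    stop("background database overlaps the activity class")
  aucs <- numeric(n_trials); seeds <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    seeds[t] <- as.integer((as.numeric(seed) * 1000 + t) %% 2147483629)
    auc <- with_seed(seeds[t], {
      samp <- sample(nrow(active_fps), n_sample)
      refs <- samp[seq_len(n_ref)]
      hits <- samp[-seq_len(n_ref)]
      pos <- knn_scores(active_fps[hits, , drop = FALSE],
                        active_fps[refs, , drop = FALSE], k)
      neg <- knn_scores(background_fps, active_fps[refs, , drop = FALSE], k)
      auc_roc(pos, neg)
    })
    aucs[t] <- auc
  }
  list(trials = data.frame(trial = seq_len(n_trials), seed = seeds, auc = aucs),
       mean_auc = mean(aucs))
}
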
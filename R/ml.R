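# Machine-learning benchmark: random forest and Tanimoto-kernel SVM
# classification with balanced-accuracy-driven grid search.

#' Confusion-matrix performance metrics
#'
#' Balanced accuracy `BA = (TPR + TNR) / 2`, Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when any
#' denominator factor is 0), `F1 = 2TP / (2TP + FP + FN)`,
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`.
#'
#' @param counts list or vector with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector (ba, mcc, f1, precision, recall).
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  if (tp + fn == 0 || tn + fp == 0)
    stop("metrics() needs at least one positive and one negative instance")
  tpr <- tp / (tp + fn); tnr <- tn / (tn + fp)
  ba <- (tpr + tnr) / 2
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tpr
  c(ba = ba, mcc = mcc, f1 = f1, precision = precision, recall = recall)
}

#' Tanimoto kernel matrix
#'
#' `K[i, j] = Tc(X[i, ], Y[j, ])`; symmetric with unit diagonal when `X == Y`
#' and rows are non-zero. The preferred SVM kernel for binary fingerprints.
#'
#' @param X,Y 0/1 fingerprint matrices with identical column count.
#' @return kernel matrix.
#' @export
tanimoto_kernel <- function(X, Y = X) tanimoto_matrix(X, Y)

RF_GRID <- expand.grid(num_trees = c(25L, 50L, 100L, 200L, 400L),
                       min_node = c(2L, 3L, 5L, 10L))
SVM_GRID <- data.frame(C = c(0.1, 1, 10, 50, 100, 200, 1000))

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    fold[ix] <- rep_len(sample(k), length(ix))[sample.int(length(ix))]
  }
  # guard: every fold must see both classes; re-stratify if not
  for (tries in 1:10) {
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2L, NA))
    if (ok) break
    warning("degenerate fold (single-class); re-stratifying")
    for (cl in unique(y)) {
      ix <- which(y == cl)
      fold[ix] <- rep_len(sample(k), length(ix))[sample.int(length(ix))]
    }
  }
  fold
}

fit_predict_rf <- function(Xtr, ytr, Xte, num_trees, min_node, seed) {
  colnames(Xtr) <- colnames(Xte) <- paste0("b", seq_len(ncol(Xtr)))
  w <- length(ytr) / (2 * table(factor(ytr, levels = c(0, 1))))
  fit <- ranger::ranger(x = Xtr, y = factor(ytr, levels = c(0, 1)),
                        num.trees = num_trees, min.node.size = min_node,
                        seed = seed, num.threads = 1L,
                        class.weights = as.numeric(w))
  as.integer(as.character(predict(fit, data = Xte,
                                  num.threads = 1L)$predictions))
}

fit_predict_svm <- function(Xtr, ytr, Xte, C) {
  K <- tanimoto_kernel(Xtr, Xtr)
  yf <- factor(ytr, levels = c(0, 1))
  cw <- length(ytr) / (2 * table(yf))          # balanced class weights
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                       C = C, class.weights = setNames(as.numeric(cw),
                                                       names(cw)))
  Kte <- tanimoto_kernel(Xte, Xtr[kernlab::SVindex(fit), , drop = FALSE])
  as.integer(as.character(kernlab::predict(fit, kernlab::as.kernelMatrix(Kte))))
}

cv_balanced_accuracy <- function(X, y, fold, fit_fn) {
  k <- max(fold)
  bas <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    pred <- fit_fn(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
    cm <- list(TP = sum(y[te] == 1 & pred == 1), TN = sum(y[te] == 0 & pred == 0),
               FP = sum(y[te] == 0 & pred == 1), FN = sum(y[te] == 1 & pred == 0))
    bas[f] <- metrics(cm)[["ba"]]
  }
  mean(bas)
}

#' Run the classification benchmark for one activity class
#'
#' Per trial: half of the actives are training positives; training negatives
#' (three times as many) are sampled from the negatives pool; hyperparameters
#' are chosen by stratified 10-fold internal cross-validation and grid search
#' maximizing mean balanced accuracy (RF: trees in 25/50/100/200/400 and
#' minimum node size 2/3/5/10, 20 candidates; SVM with Tanimoto kernel and
#' balanced class weights: C in 0.1/1/10/50/100/200/1000, 7 candidates); the
#' selected model predicts the held-out actives plus three times as many
#' fresh negatives, and metrics are computed from the confusion counts.
#'
#' @param active_fps fingerprint matrix of the activity class.
#' @param negative_fps fingerprint matrix of the negatives pool (disjoint
#'   from the actives).
#' @param model `"SVM"` or `"RF"`.
#' @param n_trials number of independent trials.
#' @param seed master seed (per-trial seeds derived by index).
#' @param cv_folds internal cross-validation folds.
#' @param permute_labels permute training labels (null-model control).
#' @return data frame, one row per trial: model, trial, seed, TP/TN/FP/FN,
#'   ba/mcc/f1/precision/recall and the chosen hyperparameters.
#' @export
run_classification <- function(active_fps, negative_fps, model = c("SVM", "RF"),
                               n_trials = 20L, seed = 1L, cv_folds = 10L,
                               permute_labels = FALSE) {
  model <- match.arg(model)
  if (nrow(active_fps) < 20L) stop("need at least 20 actives")
  if (any(rownames(active_fps) %in% rownames(negative_fps)))
    stop("negatives pool overlaps the activity class")
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    tseed <- as.integer((as.numeric(seed) * 1000 + 7 * t) %% 2147483629)
    rows[[t]] <- with_seed(tseed, {
      npos <- nrow(active_fps)
      tr_pos <- sample(npos, floor(npos / 2))
      te_pos <- setdiff(seq_len(npos), tr_pos)
      nneg_tr <- 3L * length(tr_pos); nneg_te <- 3L * length(te_pos)
      if (nrow(negative_fps) < nneg_tr + nneg_te)
        stop("negatives pool too small: need ", nneg_tr + nneg_te)
      negs <- sample(nrow(negative_fps), nneg_tr + nneg_te)
      Xtr <- rbind(active_fps[tr_pos, , drop = FALSE],
                   negative_fps[negs[seq_len(nneg_tr)], , drop = FALSE])
      ytr <- c(rep(1L, length(tr_pos)), rep(0L, nneg_tr))
      if (permute_labels) ytr <- sample(ytr)
      Xte <- rbind(active_fps[te_pos, , drop = FALSE],
                   negative_fps[negs[-seq_len(nneg_tr)], , drop = FALSE])
      yte <- c(rep(1L, length(te_pos)), rep(0L, nneg_te))
      fold <- stratified_folds(ytr, cv_folds)
      if (model == "RF") {
        scores <- apply(RF_GRID, 1, function(g)
          cv_balanced_accuracy(Xtr, ytr, fold, function(Xa, ya, Xb)
            fit_predict_rf(Xa, ya, Xb, g[["num_trees"]], g[["min_node"]],
                           seed = tseed)))
        best <- RF_GRID[which.max(scores), ]
        pred <- fit_predict_rf(Xtr, ytr, Xte, best$num_trees, best$min_node,
                               seed = tseed)
        hp <- sprintf("num_trees=%d;min_node=%d", best$num_trees, best$min_node)
      } else {
        scores <- vapply(SVM_GRID$C, function(C)
          cv_balanced_accuracy(Xtr, ytr, fold, function(Xa, ya, Xb)
            fit_predict_svm(Xa, ya, Xb, C)), 0)
        bestC <- SVM_GRID$C[which.max(scores)]
        pred <- fit_predict_svm(Xtr, ytr, Xte, bestC)
        hp <- sprintf("C=%g", bestC)
      }
      cm <- list(TP = sum(yte == 1 & pred == 1), TN = sum(yte == 0 & pred == 0),
                 FP = sum(yte == 0 & pred == 1), FN = sum(yte == 1 & pred == 0))
      met <- metrics(cm)
      data.frame(model = model, trial = t, seed = tseed,
                 TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN,
                 ba = met[["ba"]], mcc = met[["mcc"]], f1 = met[["f1"]],
                 precision = met[["precision"]], recall = met[["recall"]],
                 hyperparameters = hp, stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test over paired per-class performance values (the
#' significance test of the benchmark protocol). All-zero differences are a
#' defined-degenerate case: p = 1 with a warning.
#'
#' @param paired_a,paired_b numeric vectors of equal length (>= 5).
#' @return two-sided p-value.
#' @export
wilcoxon_compare <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 5L)
  d <- paired_a - paired_b
  if (all(d == 0)) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(paired_a, paired_b, paired = TRUE, exact = FALSE)$p.value)
}
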
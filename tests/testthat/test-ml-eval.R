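test_that("confusion metrics follow the benchmark formulas", {
  perfect <- metrics(list(TP = 50, TN = 150, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("ba", "mcc", "f1")]), c(1, 1, 1))

  chance <- metrics(list(TP = 25, FN = 25, TN = 75, FP = 75))
  expect_equal(chance[["ba"]], 0.5)
  expect_equal(chance[["mcc"]], 0)

  m <- metrics(list(TP = 90, FP = 10, FN = 10, TN = 290))
  expect_equal(m[["precision"]], 0.9)
  expect_equal(m[["recall"]], 0.9)
  expect_equal(m[["f1"]], 0.9)

  # denominator-zero convention: a classifier predicting one class only
  allneg <- metrics(list(TP = 0, FN = 20, TN = 60, FP = 0))
  expect_equal(allneg[["mcc"]], 0)
  expect_equal(allneg[["ba"]], 0.5)

  expect_error(metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "at least one")
})

test_that("metrics agree with a per-instance recount oracle", {
  set.seed(6)
  for (r in 1:10) {
    truth <- rbinom(200, 1, 0.25)
    pred <- ifelse(runif(200) < 0.8, truth, 1 - truth)
    if (sum(truth) == 0 || sum(truth) == 200) next
    cm <- list(TP = sum(truth & pred), TN = sum(!truth & !pred),
               FP = sum(!truth & pred), FN = sum(truth & !pred))
    m <- metrics(cm)
    tpr <- mean(pred[truth == 1] == 1); tnr <- mean(pred[truth == 0] == 0)
    expect_equal(m[["ba"]], (tpr + tnr) / 2)
    expect_equal(m[["mcc"]],
                 suppressWarnings(cor(truth, pred)), tolerance = 1e-12)
  }
})

test_that("the Tanimoto kernel is consistent with pairwise similarities", {
  set.seed(7)
  X <- matrix(rbinom(5 * 12, 1, 0.5), 5)
  K <- tanimoto_kernel(X)
  expect_equal(diag(K), rep(1, 5), ignore_attr = TRUE)
  for (i in 1:5) for (j in 1:5)
    expect_equal(K[i, j], tanimoto(X[i, ], X[j, ]))
  A <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 0))
  expect_equal(tanimoto_kernel(A)[1, 2], 0)
})

test_that("hyperparameter grids match the published protocol", {
  expect_equal(nrow(csfpr:::RF_GRID), 20L)
  expect_setequal(unique(csfpr:::RF_GRID$num_trees), c(25, 50, 100, 200, 400))
  expect_setequal(unique(csfpr:::RF_GRID$min_node), c(2, 3, 5, 10))
  expect_equal(nrow(csfpr:::SVM_GRID), 7L)
  expect_setequal(csfpr:::SVM_GRID$C, c(0.1, 1, 10, 50, 100, 200, 1000))
})

test_that("a Tanimoto-kernel SVM separates disjoint bit classes at large C", {
  set.seed(11)
  Xa <- cbind(matrix(rbinom(20 * 8, 1, 0.8), 20), matrix(0L, 20, 8))
  Xb <- cbind(matrix(0L, 20, 8), matrix(rbinom(20 * 8, 1, 0.8), 20))
  X <- rbind(Xa, Xb); y <- rep(c(1L, 0L), each = 20)
  pred <- csfpr:::fit_predict_svm(X, y, X, C = 1000)
  expect_equal(metrics(list(TP = sum(y & pred), TN = sum(!y & !pred),
                            FP = sum(!y & pred), FN = sum(y & !pred)))[["ba"]],
               1)
})

test_that("classification runs are reproducible bit-for-bit", {
  set.seed(12)
  core <- c(rep(1L, 10), rep(0L, 22))
  act <- t(vapply(1:24, function(i) { v <- core; v[sample(11:32, 3)] <- 1L; v },
                  integer(32)))
  rownames(act) <- paste0("a", 1:24)
  neg <- matrix(rbinom(150 * 32, 1, 0.2), 150)
  neg[, 1:10] <- 0L
  rownames(neg) <- paste0("n", 1:150)
  r1 <- run_classification(act, neg, model = "SVM", n_trials = 2, seed = 5)
  r2 <- run_classification(act, neg, model = "SVM", n_trials = 2, seed = 5)
  expect_identical(r1, r2)
  expect_gt(mean(r1$ba), 0.9)
  expect_error(run_classification(act[1:10, ], neg, model = "SVM", seed = 1),
               "at least 20")
})

test_that("the Wilcoxon comparison flags offsets and degenerate pairs", {
  set.seed(13)
  a <- runif(30)
  expect_lt(wilcoxon_compare(a + 0.1, a), 0.05)
  expect_warning(p <- wilcoxon_compare(a, a), "zero")
  expect_equal(p, 1)
  expect_error(wilcoxon_compare(1:3, 1:3))
})
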
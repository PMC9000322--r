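test_that("knn scoring takes the max for k = 1 and top-k means otherwise", {
  refs <- diag(10)[1:3, ]                       # orthogonal references
  expect_equal(knn_score(diag(10)[1, ], refs, k = 1), 1)
  # probe sharing 4, 2 and 0 of its 4 bits with three 4-bit references:
  # Tc = 1, 1/3, 0
  probe <- c(rep(1L, 4), rep(0L, 8))
  refs2 <- rbind(c(rep(1L, 4), rep(0L, 8)),
                 c(1L, 1L, 0L, 0L, 1L, 1L, rep(0L, 6)),
                 c(rep(0L, 8), rep(1L, 4)))
  expect_equal(knn_score(probe, refs2, k = 1), 1)
  expect_equal(knn_score(probe, refs2, k = 2), (1 + 1 / 3) / 2)
  expect_equal(knn_score(probe, refs2, k = 3), (1 + 1 / 3 + 0) / 3)
  # constant similarity list is invariant in k
  same <- rbind(probe, probe, probe)
  for (k in 1:3) expect_equal(knn_score(probe, same, k), 1)
  expect_error(knn_score(rep(1, 4), diag(4)[1:2, ], k = 3), "k must be")
})

test_that("knn score of k = 1 dominates larger k", {
  set.seed(3)
  for (r in 1:20) {
    db <- matrix(rbinom(16, 1, 0.5), 1)
    refs <- matrix(rbinom(10 * 16, 1, 0.5), 10)
    s1 <- knn_score(db[1, ], refs, 1)
    for (k in c(2, 5, 10)) expect_gte(s1, knn_score(db[1, ], refs, k))
  }
})

test_that("AUC follows the Mann-Whitney formulation with half-credit ties", {
  expect_equal(auc_roc(c(2, 3), c(1)), 1)
  expect_equal(auc_roc(c(1, 1, 1), c(1, 1)), 0.5)
  expect_equal(auc_roc(c(3, 1), c(2)), 0.5)       # (1 + 0) / 2
  expect_equal(auc_roc(c(1), c(2, 3)), 0)
  expect_error(auc_roc(numeric(), 1), "non-empty")
  # invariance under strictly monotone transforms
  set.seed(4)
  pos <- runif(40); neg <- runif(60)
  expect_equal(auc_roc(pos, neg), auc_roc(exp(3 * pos), exp(3 * neg)))
  expect_equal(auc_roc(pos, neg), auc_roc(rank(c(pos, neg))[1:40],
                                          rank(c(pos, neg))[41:100]))
})

test_that("trials separate constructed hits from decoys and are reproducible", {
  set.seed(8)
  core <- c(rep(1L, 12), rep(0L, 28))
  actives <- t(vapply(1:30, function(i) {
    v <- core; v[sample(13:40, 4)] <- 1L; v
  }, integer(40)))
  rownames(actives) <- paste0("a", 1:30)
  decoys <- matrix(rbinom(200 * 40, 1, 0.15), 200)
  decoys[, 1:12] <- 0L
  rownames(decoys) <- paste0("d", 1:200)
  res <- run_trials(actives, decoys, k = 1, n_trials = 5, n_sample = 20,
                    n_ref = 5, seed = 9)
  expect_gt(res$mean_auc, 0.95)
  res2 <- run_trials(actives, decoys, k = 1, n_trials = 5, n_sample = 20,
                     n_ref = 5, seed = 9)
  expect_identical(res, res2)
  expect_error(run_trials(actives, decoys, n_sample = 100, seed = 1),
               "insufficient")
  overlap <- decoys; rownames(overlap)[1] <- "a1"
  expect_error(run_trials(actives, overlap, n_sample = 20, n_ref = 5, seed = 1),
               "overlaps")
})
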
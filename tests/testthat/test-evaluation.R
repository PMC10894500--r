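test_that("k-fold splits partition positives and sample disjoint negatives", {
  ds <- random_dataset(10, 6, seed = 13, density = 0.35)
  k <- 5L
  sp <- kfold_splits(ds, k = k, seed = 2)
  lin <- function(cells) (cells[, 2] - 1L) * nrow(ds$A) + cells[, 1]

  test_pos <- unlist(lapply(sp$folds, function(f) lin(f$test_pos)))
  expect_setequal(test_pos, which(ds$A == 1))
  expect_equal(anyDuplicated(test_pos), 0L)

  sizes <- vapply(sp$folds, function(f) nrow(f$test_pos), integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)

  for (f in sp$folds) {
    expect_equal(nrow(f$train_neg), nrow(f$train_pos))
    expect_equal(nrow(f$test_neg), nrow(f$test_pos))
    negs <- c(lin(f$train_neg), lin(f$test_neg))
    expect_true(all(ds$A[f$train_neg] == 0))
    expect_true(all(ds$A[f$test_neg] == 0))
    expect_equal(anyDuplicated(negs), 0L)
    expect_equal(length(intersect(lin(f$train_pos), lin(f$test_pos))), 0L)
  }

  sp2 <- kfold_splits(ds, k = k, seed = 2)
  expect_identical(sp, sp2)

  # 10 positives, k = 5 -> folds of size 2
  recs <- data.frame(mirna = sprintf("m%02d", 1:10),
                     stress = rep(sprintf("s%d", 1:5), 2),
                     sequence = random_rna(10, seed = 30))
  dsx <- build_association_dataset(recs)
  spx <- kfold_splits(dsx, k = 5, seed = 1)
  expect_true(all(vapply(spx$folds, function(f) nrow(f$test_pos),
                         integer(1)) == 2L))
})

test_that("confusion-based metrics match the printed formulas", {
  # TP=2, FP=1, FN=1, TN=2
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.05)
  mr <- compute_metrics(labels, scores, threshold = 0.5)
  expect_equal(c(mr$TP, mr$FP, mr$FN, mr$TN), c(2, 1, 1, 2))
  expect_equal(mr$precision, 2 / 3)
  expect_equal(mr$recall, 2 / 3)
  expect_equal(mr$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(mr$accuracy, 4 / 6)
  expect_equal(mr$specificity, 2 / 3)

  sep <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auc, 1)
  expect_equal(sep$aupr, 1)

  ident <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(ident$specificity, 1)

  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)), "one class")
})

test_that("AUC/AUPR agree with a brute-force threshold sweep and pROC", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 60
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)       # force ties
    mr <- compute_metrics(labels, scores)
    bf <- brute_auc_aupr(labels, scores)
    expect_equal(mr$auc, bf$auc, tolerance = 1e-9)
    expect_equal(mr$aupr, bf$aupr, tolerance = 1e-9)
    proc <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                 direction = "<")))
    expect_equal(mr$auc, as.numeric(proc), tolerance = 1e-9)
  }
})

test_that("ranking metrics are invariant to monotone transforms and permutations", {
  set.seed(3)
  labels <- rbinom(100, 1, 0.4)
  scores <- runif(100)
  m1 <- compute_metrics(labels, scores)
  m2 <- compute_metrics(labels, plogis(5 * scores - 2))  # strictly monotone
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  expect_equal(m1$aupr, m2$aupr, tolerance = 1e-12)
  perm <- sample(100)
  m3 <- compute_metrics(labels[perm], scores[perm])
  expect_equal(m1$auc, m3$auc, tolerance = 1e-12)
  expect_equal(m1$aupr, m3$aupr, tolerance = 1e-12)
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(2024)
  labels <- rep(c(0, 1), 500)
  scores <- runif(1000)
  expect_lt(abs(compute_metrics(labels, scores)$auc - 0.5), 0.05)
})

test_that("pair features concatenate the MS row with the SS row", {
  MS <- random_sim(2, seed = 1, kind = "integrated_m")
  SS <- random_sim(3, seed = 2, kind = "integrated_s")
  pf <- build_pair_features(MS, SS, cbind(1, 1))
  expect_equal(ncol(pf) - 2L, 5L)
  expect_equal(as.numeric(pf[1, 3:4]), unname(unclass(MS)[1, ]))
  expect_equal(as.numeric(pf[1, 5:7]), unname(unclass(SS)[1, ]))
  grid <- as.matrix(expand.grid(1:2, 1:3))
  expect_equal(nrow(build_pair_features(MS, SS, grid)), 6L)
  expect_error(build_pair_features(MS, SS, cbind(3, 1)), "out of range")
})

test_that("prediction ranking skips known pairs and breaks ties by id", {
  scores <- matrix(c(0.9, 0.9, 0.2, 0.8), 2, 2,
                   dimnames = list(c("mirB", "mirA"), c("s1", "s2")))
  A <- matrix(c(0L, 0L, 1L, 0L), 2, 2, dimnames = dimnames(scores))
  out <- rank_predictions(scores, A, top_k = 2)
  s1 <- out[out$stress == "s1", ]
  expect_equal(s1$mirna, c("mirA", "mirB"))        # tie -> lexicographic
  s2 <- out[out$stress == "s2", ]
  expect_equal(s2$mirna, "mirA")                   # known cell excluded
  allknown <- rank_predictions(scores, matrix(1L, 2, 2, dimnames = dimnames(A)))
  expect_equal(nrow(allknown), 0L)
  top1 <- rank_predictions(scores, A, top_k = 1)
  expect_true(all(top1$rank == 1))
})
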
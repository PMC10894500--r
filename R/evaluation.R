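#' k-fold cross-validation splits with negative sampling
#'
#' Shuffles the positive cells of the association matrix with the given
#' seed and partitions them into k near-equal folds. For every fold,
#' negatives are drawn uniformly without replacement from the zero cells
#' of A, matched `negative_ratio`:1 to the positives within the training
#' and test sets separately (train and test negatives are disjoint).
#'
#' @param dataset an `association_dataset`.
#' @param k number of folds (default 5).
#' @param negative_ratio negatives per positive (default 1).
#' @param seed RNG seed.
#' @return a `fold_splits` object: list with `k`, `seed` and `folds`, a
#'   list of per-fold lists holding integer cell-index matrices
#'   `train_pos`, `test_pos`, `train_neg`, `test_neg` (columns: miRNA
#'   row, stress column).
#' @export
kfold_splits <- function(dataset, k = 5L, negative_ratio = 1, seed = 1L) {
  A <- dataset$A
  pos <- which(A == 1)
  zero <- which(A == 0)
  if (length(pos) < k) stop("fewer positives than folds")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos <- sample(pos)
  fold_id <- rep(seq_len(k), length.out = length(pos))
  as_cells <- function(lin) {
    cbind(row = ((lin - 1L) %% nrow(A)) + 1L,
          col = ((lin - 1L) %/% nrow(A)) + 1L)
  }
  folds <- lapply(seq_len(k), function(f) {
    test_pos <- pos[fold_id == f]
    train_pos <- pos[fold_id != f]
    n_neg <- ceiling(negative_ratio * c(length(train_pos), length(test_pos)))
    if (sum(n_neg) > length(zero)) {
      stop("not enough zero cells to sample ", sum(n_neg), " negatives")
    }
    negs <- sample(zero, sum(n_neg))
    list(train_pos = as_cells(train_pos),
         test_pos = as_cells(test_pos),
         train_neg = as_cells(negs[seq_len(n_neg[1])]),
         test_neg = as_cells(negs[n_neg[1] + seq_len(n_neg[2])]))
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 negative_ratio = negative_ratio, folds = folds,
                 dim = dim(A)),
            class = "fold_splits")
}

#' Classification and ranking metrics
#'
#' Confusion counts at the given threshold and the derived precision,
#' recall, specificity, F1 (`2TP / (2TP + FN + FP)`) and accuracy, plus
#' threshold-free AUC (trapezoid over the exact ROC step curve) and
#' AUPR (step-wise precision-recall area, no interpolation).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold for the confusion-based metrics
#'   (default 0.5; scores >= threshold are called positive).
#' @return a `metrics_report` list: TP, FP, TN, FN, precision, recall,
#'   specificity, f1, accuracy, auc, aupr, threshold.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("label/score length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop("AUC/AUPR undefined: only one class present")
  }
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    precision = if (TP + FP > 0) TP / (TP + FP) else 0,
    recall = TP / (TP + FN),
    specificity = TN / (TN + FP),
    f1 = 2 * TP / (2 * TP + FN + FP),
    accuracy = (TP + TN) / length(labels),
    auc = .roc_auc(labels, scores),
    aupr = .pr_auc(labels, scores),
    threshold = threshold
  ), class = "metrics_report")
}

# ROC area by trapezoid over the exact step curve (ties grouped by
# distinct score value; equivalent to the Mann-Whitney statistic with
# ties counted 1/2).
.roc_auc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp_last <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1 - y)[grp_last]
  P <- sum(labels); N <- length(labels) - P
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Precision-recall area by right-continuous steps: sum over threshold
# points of (delta recall) * precision at that point.
.pr_auc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp_last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1 - y)[grp_last]
  P <- sum(labels)
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: AUPR %.4f AUC %.4f F1 %.4f ACC %.4f RE %.4f SPE %.4f PRE %.4f (thr %.2f)\n",
    x$aupr, x$auc, x$f1, x$accuracy, x$recall, x$specificity,
    x$precision, x$threshold))
  invisible(x)
}

#' Pipeline configuration for cross-validation and prediction
#'
#' Bundles every tunable of the similarity, network, and model stages.
#'
#' @param embedding_dim word-embedding dimensionality (default 100).
#' @param grid_size CGR grid size N (default 8).
#' @param mirna_weights alpha weights for (seq, func, gipk_m).
#' @param stress_weights beta weights for (sem, gipk_s).
#' @param restart_prob RWR restart probability (default 0.7).
#' @param rwr_tol,rwr_max_iter RWR convergence controls.
#' @param features `"rwr"` (default; RWR steady-state rows) or
#'   `"hetnet"` (rows of H directly) as encoder input.
#' @param encoder an `encoder_config`.
#' @param train a `train_config`.
#' @param threshold decision threshold for threshold-based metrics.
#' @param seed base seed for embeddings and folds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(embedding_dim = 100L, grid_size = 8L,
                            mirna_weights = c(1, 1, 1),
                            stress_weights = c(1, 1),
                            restart_prob = 0.7, rwr_tol = 1e-6,
                            rwr_max_iter = 1000L,
                            features = c("rwr", "hetnet"),
                            encoder = encoder_config(),
                            train = train_config(),
                            threshold = 0.5, seed = 1L) {
  features <- match.arg(features)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 grid_size = as.integer(grid_size),
                 mirna_weights = mirna_weights,
                 stress_weights = stress_weights,
                 restart_prob = restart_prob, rwr_tol = rwr_tol,
                 rwr_max_iter = as.integer(rwr_max_iter),
                 features = features, encoder = encoder, train = train,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Similarity + network + feature stages for one (possibly masked)
# association matrix. sem and seq do not depend on A and are passed in.
.pipeline_stage <- function(dataset, A, sem, seqsim, config) {
  func <- functional_similarity(dataset, sem, A_override = A)
  gm <- gipk_matrix(A, "gipk_m")
  gs <- gipk_matrix(t(A), "gipk_s")
  MS <- integrate_mirna_similarity(seqsim, func, gm,
                                   weights = config$mirna_weights)
  SS <- integrate_stress_similarity(sem, gs, weights = config$stress_weights)
  net <- build_heterogeneous_network(MS, SS, A)
  X <- if (config$features == "rwr") {
    rwr_steady_state(net, restart_prob = config$restart_prob,
                     tol = config$rwr_tol,
                     max_iter = config$rwr_max_iter)$P
  } else {
    net$H
  }
  list(net = net, X = X, MS = MS, SS = SS)
}

#' Cross-validate the full pipeline
#'
#' Runs k-fold cross-validation of the similarity -> heterogeneous
#' network -> RWR -> graph-autoencoder pipeline. Under the `strict`
#' leakage policy the association-derived similarities (functional,
#' both GIPKs), the network and the RWR features are recomputed for each
#' fold with the test positives zeroed out of A; under `paperlike` they
#' are computed once from the full A (train/test splitting then applies
#' only to the autoencoder loss and the scored cells), which leaks
#' test-edge information into the features and inflates the metrics.
#'
#' @param dataset an `association_dataset`.
#' @param config a `pipeline_config`.
#' @param k folds (default 5).
#' @param policy `"strict"` (default) or `"paperlike"`.
#' @param embeddings optional pre-trained `embedding_table`; trained on
#'   the dataset's stress terms when omitted.
#' @return a `cv_report`: list with `per_fold` (data.frame, one row per
#'   fold), `mean` (named numeric), `policy`, `k`.
#' @export
cross_validate <- function(dataset, config = pipeline_config(), k = 5L,
                           policy = c("strict", "paperlike"),
                           embeddings = NULL) {
  policy <- match.arg(policy)
  if (is.null(embeddings)) {
    embeddings <- train_stress_embeddings(dataset$stress_terms,
                                          dim = config$embedding_dim,
                                          seed = config$seed)
  }
  sem <- semantic_similarity(dataset, embeddings)
  seqsim <- sequence_similarity(dataset, grid_size = config$grid_size)
  splits <- kfold_splits(dataset, k = k,
                         negative_ratio = config$train$negative_ratio,
                         seed = config$seed)
  m <- nrow(dataset$A); n <- ncol(dataset$A)

  shared <- if (policy == "paperlike") {
    .pipeline_stage(dataset, dataset$A, sem, seqsim, config)
  } else NULL

  rows <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- splits$folds[[f]]
    if (policy == "strict") {
      A_tr <- dataset$A
      A_tr[fold$test_pos] <- 0L
      stage <- .pipeline_stage(dataset, A_tr, sem, seqsim, config)
    } else {
      stage <- shared
    }
    cells <- rbind(fold$train_pos, fold$train_neg)
    yv <- c(rep(1, nrow(fold$train_pos)), rep(0, nrow(fold$train_neg)))
    enc <- config$encoder
    enc$seed <- config$encoder$seed + f   # independent init per fold
    model <- train_gae(stage$X, stage$net$H, cells, yv, m, n,
                       config = enc, train = config$train)
    test_cells <- rbind(fold$test_pos, fold$test_neg)
    yt <- c(rep(1, nrow(fold$test_pos)), rep(0, nrow(fold$test_neg)))
    st <- model$scores[test_cells]
    mr <- compute_metrics(yt, st, threshold = config$threshold)
    rows[[f]] <- data.frame(fold = f, aupr = mr$aupr, auc = mr$auc,
                            f1 = mr$f1, acc = mr$accuracy,
                            recall = mr$recall, spe = mr$specificity,
                            pre = mr$precision)
  }
  per_fold <- do.call(rbind, rows)
  mean_row <- colMeans(per_fold[, -1L])
  structure(list(per_fold = per_fold, mean = mean_row, policy = policy,
                 k = as.integer(k)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", x$policy, ", k = ", x$k, ")\n", sep = "")
  print(round(x$per_fold, 4), row.names = FALSE)
  cat("mean:", paste(names(x$mean),
                     sprintf("%.4f", x$mean), collapse = "  "), "\n")
  invisible(x)
}

#' Concatenated pair features for external classifiers
#'
#' For each (i, j) pair, concatenates row i of the integrated miRNA
#' similarity MS with row j of the integrated stress similarity SS into
#' one feature vector of length m + n.
#'
#' @param MS integrated miRNA similarity (m x m).
#' @param SS integrated stress similarity (n x n).
#' @param pairs integer matrix (L x 2) of (miRNA row, stress column).
#' @return data.frame with `mirna`, `stress` labels and the m + n
#'   feature columns.
#' @export
build_pair_features <- function(MS, SS, pairs) {
  m <- nrow(MS); n <- nrow(SS)
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > m) ||
      any(pairs[, 2L] < 1L | pairs[, 2L] > n)) {
    stop("pair index out of range")
  }
  feats <- cbind(unclass(MS)[pairs[, 1L], , drop = FALSE],
                 unclass(SS)[pairs[, 2L], , drop = FALSE])
  colnames(feats) <- c(paste0("ms_", seq_len(m)), paste0("ss_", seq_len(n)))
  mn <- rownames(MS); sn <- rownames(SS)
  data.frame(
    mirna = if (is.null(mn)) pairs[, 1L] else mn[pairs[, 1L]],
    stress = if (is.null(sn)) pairs[, 2L] else sn[pairs[, 2L]],
    feats, check.names = FALSE, row.names = NULL)
}

#' Rank novel candidate associations
#'
#' Per stress, sorts the unobserved (A = 0) miRNA cells by descending
#' predicted score and returns the top ranks; ties are broken by
#' lexicographic miRNA id.
#'
#' @param scores m x n matrix of predicted probabilities with dimnames.
#' @param A binary matrix of known associations (same shape).
#' @param top_k candidates to keep per stress (default 10).
#' @return data.frame (stress, mirna, score, rank).
#' @export
rank_predictions <- function(scores, A, top_k = 10L) {
  stopifnot(identical(dim(scores), dim(A)))
  out <- list()
  for (j in seq_len(ncol(scores))) {
    cand <- which(A[, j] == 0)
    if (length(cand) == 0L) next
    ids <- rownames(scores)[cand]
    ord <- order(-scores[cand, j], ids)
    keep <- utils::head(ord, top_k)
    out[[j]] <- data.frame(stress = colnames(scores)[j],
                           mirna = ids[keep],
                           score = scores[cand[keep], j],
                           rank = seq_along(keep), row.names = NULL)
  }
  if (length(out) == 0L) {
    return(data.frame(stress = character(), mirna = character(),
                      score = numeric(), rank = integer()))
  }
  do.call(rbind, out)
}
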
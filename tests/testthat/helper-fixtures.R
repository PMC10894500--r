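# Small programmatic fixtures shared across tests.

random_rna <- function(n, len = 22L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# A tiny hand-built association dataset: 3 miRNAs x 3 stresses.
tiny_dataset <- function() {
  records <- data.frame(
    mirna = c("mirA", "mirA", "mirB", "mirC"),
    stress = c("cold stress", "drought", "drought", "salt stress"),
    sequence = c("ACGUACGUACGUACGUACGUAC", "ACGUACGUACGUACGUACGUAC",
                 "UUGGCCAAUUGGCCAAUUGGCA", "GGGCCCAAAUUUGGGCCCAAAU"),
    stringsAsFactors = FALSE)
  build_association_dataset(records)
}

# A random small dataset for property tests.
random_dataset <- function(m = 8L, n = 5L, seed = 1L, density = 0.4) {
  set.seed(seed)
  repeat {
    A <- matrix(rbinom(m * n, 1L, density), m, n)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  ids <- sprintf("mir%02d", seq_len(m))
  terms <- paste(c("cold", "heat", "salt", "drought", "light",
                   "flood", "copper", "ozone")[seq_len(n)], "stress")
  idx <- which(A == 1, arr.ind = TRUE)
  records <- data.frame(mirna = ids[idx[, 1]], stress = terms[idx[, 2]],
                        stringsAsFactors = FALSE)
  seqs <- random_rna(m, seed = seed + 100L)
  names(seqs) <- ids
  build_association_dataset(records, sequences = seqs)
}

# Random symmetric similarity matrix with unit diagonal.
random_sim <- function(n, seed = 1L, kind = "sem", ids = NULL) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  if (is.null(ids)) ids <- sprintf("node%02d", seq_len(n))
  dimnames(M) <- list(ids, ids)
  similarity_matrix(M, kind)
}

# Brute-force Wang-style functional similarity straight from the formula.
brute_func <- function(A, sem) {
  m <- nrow(A)
  out <- diag(1, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    Si <- which(A[i, ] == 1); Sj <- which(A[j, ] == 1)
    tot <- length(Si) + length(Sj)
    if (tot == 0) { out[i, j] <- 0; next }
    s <- 0
    for (st in Si) s <- s + (if (length(Sj)) max(sem[st, Sj]) else 0)
    for (st in Sj) s <- s + (if (length(Si)) max(sem[st, Si]) else 0)
    out[i, j] <- s / tot
  }
  out
}

# Brute-force GIPK straight from the exponential formula.
brute_gipk <- function(P) {
  gamma <- nrow(P) / sum(rowSums(P^2))
  K <- matrix(0, nrow(P), nrow(P))
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(P))) {
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  }
  K
}

# Brute-force per-node GIN layer loop.
brute_gin_layer <- function(h, W, eps, mlp, aggregator) {
  out <- NULL
  for (v in seq_len(nrow(h))) {
    agg <- rep(0, ncol(h))
    for (u in seq_len(nrow(h))) agg <- agg + W[v, u] * h[u, ]
    if (aggregator == "mean") {
      d <- sum(W[v, ])
      agg <- if (d > 0) agg / d else agg * 0
    }
    row <- mlp(matrix((1 + eps) * h[v, ] + agg, 1L))
    out <- rbind(out, row)
  }
  out
}

# Brute-force AUC/AUPR by an explicit confusion sweep over all
# distinct-score thresholds.
brute_auc_aupr <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels); N <- sum(1 - labels)
  tpr <- fpr <- rec <- prec <- numeric(length(thr))
  for (t in seq_along(thr)) {
    pred <- scores >= thr[t]
    TP <- sum(pred & labels == 1); FP <- sum(pred & labels == 0)
    tpr[t] <- TP / P; fpr[t] <- FP / N
    rec[t] <- TP / P; prec[t] <- TP / (TP + FP)
  }
  auc <- sum(diff(c(0, fpr)) * (c(0, head(tpr, -1)) + tpr) / 2)
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, aupr = aupr)
}
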
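#' Construct a labeled similarity matrix
#'
#' @param values square numeric matrix with dimnames.
#' @param kind one of `sem`, `func`, `seq`, `gipk_m`, `gipk_s`,
#'   `integrated_m`, `integrated_s`.
#' @return a `similarity_matrix` (the matrix with `kind` and class
#'   attributes).
#' @export
similarity_matrix <- function(values, kind) {
  kind <- match.arg(kind, c("sem", "func", "seq", "gipk_m", "gipk_s",
                            "integrated_m", "integrated_s"))
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(!is.finite(values))) stop("non-finite similarity values")
  if (max(abs(values - t(values))) > 1e-10) {
    stop("similarity matrix is not symmetric")
  }
  values <- (values + t(values)) / 2   # kill representation-level asymmetry
  structure(values, kind = kind, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (", attr(x, "kind"), "): ",
      nrow(x), " x ", ncol(x), "\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

.sim_ids <- function(sim) rownames(sim)

#' Semantic similarity of abiotic-stress terms
#'
#' Cosine similarity between the embedding vectors of every pair of
#' stress terms; the diagonal is exactly 1.
#'
#' @param dataset an `association_dataset`.
#' @param table an `embedding_table` covering the dataset's stress terms.
#' @return `similarity_matrix` of kind `sem` over the stress terms.
#' @export
semantic_similarity <- function(dataset, table) {
  terms <- dataset$stress_terms
  vecs <- t(vapply(terms, function(tm) stress_vector(tm, table),
                   numeric(table$dim)))
  norms <- sqrt(rowSums(vecs^2))
  zero <- norms == 0
  if (any(zero)) {
    stop("zero-norm embedding vector for term(s): ",
         paste(terms[zero], collapse = ", "))
  }
  unit <- vecs / norms
  S <- unit %*% t(unit)
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(terms, terms)
  similarity_matrix(S, "sem")
}

#' Similarity between a stress and a stress set
#'
#' Best-match rule: the maximum semantic similarity between `st` and the
#' members of `ST`; 0 for an empty set (so miRNAs with no associations
#' in a training fold contribute nothing rather than dividing by zero).
#'
#' @param st index of a stress (into the `sem` matrix).
#' @param ST integer vector of stress indices.
#' @param sem semantic `similarity_matrix`.
#' @return scalar similarity.
#' @export
stress_set_similarity <- function(st, ST, sem) {
  if (length(ST) == 0L) return(0)
  max(sem[st, ST])
}

#' Functional similarity of miRNAs from shared stress responses
#'
#' Wang-style measure: for miRNAs with stress sets ST1 (size m) and ST2
#' (size n), the similarity is the sum of best-match similarities of
#' each stress in ST1 against ST2 and vice versa, divided by m + n.
#' Defined as 0 when both sets are empty; the diagonal is forced to 1.
#'
#' @param dataset an `association_dataset` (stress sets come from its
#'   adjacency matrix, or from `A_override` when given).
#' @param sem semantic `similarity_matrix` over the dataset's stresses.
#' @param A_override optional 0/1 matrix to take stress sets from (used
#'   by leakage-safe cross-validation).
#' @return `similarity_matrix` of kind `func` over the miRNAs.
#' @export
functional_similarity <- function(dataset, sem, A_override = NULL) {
  A <- if (is.null(A_override)) dataset$A else A_override
  stopifnot(ncol(A) == nrow(sem))
  m <- nrow(A)
  sets <- lapply(seq_len(m), function(i) which(A[i, ] == 1))
  Fm <- diag(1, m)
  for (i in seq_len(m)) {
    Si <- sets[[i]]
    for (j in seq_len(i - 1L)) {
      Sj <- sets[[j]]
      tot <- length(Si) + length(Sj)
      if (tot == 0L) { val <- 0 } else {
        sub <- sem[Si, Sj, drop = FALSE]
        val <- (sum(apply(sub, 1L, max0)) + sum(apply(sub, 2L, max0))) / tot
      }
      Fm[i, j] <- Fm[j, i] <- val
    }
  }
  dimnames(Fm) <- list(dataset$mirna_ids, dataset$mirna_ids)
  similarity_matrix(Fm, "func")
}

# max of a vector, 0 when empty (best-match against an empty set)
max0 <- function(x) if (length(x) == 0L) 0 else max(x)

#' Sequence similarity of miRNAs via CGR grid features
#'
#' Each sequence is mapped to its chaos-game trajectory, summarized as a
#' 3 N^2 grid feature vector, and pairs are compared with the Pearson
#' correlation coefficient.
#'
#' @param dataset an `association_dataset` with sequences.
#' @param grid_size N, CGR grid cells per axis (default 8).
#' @return `similarity_matrix` of kind `seq` over the miRNAs.
#' @export
sequence_similarity <- function(dataset, grid_size = 8L) {
  ids <- dataset$mirna_ids
  feats <- t(vapply(ids, function(id) {
    cgr_feature_vector(cgr_trajectory(dataset$sequences[[id]]),
                       grid_size)$vector
  }, numeric(3L * grid_size^2)))
  sds <- apply(feats, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance CGR feature vector for miRNA(s): ",
         paste(ids[sds == 0], collapse = ", "))
  }
  S <- stats::cor(t(feats))
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  similarity_matrix(S, "seq")
}

#' Gaussian interaction profile kernel similarity
#'
#' For profile rows V_i (rows of the association matrix for miRNAs,
#' columns for stresses), the kernel is exp(-gamma * ||V_i - V_j||^2)
#' with bandwidth gamma = (number of profiles) / sum_i ||V_i||^2, i.e.
#' the reciprocal of the mean squared profile norm.
#'
#' @param profiles numeric 0/1 matrix, one profile per row.
#' @param kind `"gipk_m"` or `"gipk_s"` tag for the result.
#' @return `similarity_matrix` of the requested kind.
#' @export
gipk_matrix <- function(profiles, kind = c("gipk_m", "gipk_s")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(profiles))
  ssq <- sum(profiles^2)
  if (ssq == 0) stop("all-zero profile matrix: GIPK bandwidth undefined")
  gamma <- nrow(profiles) / ssq
  D2 <- as.matrix(stats::dist(profiles))^2
  K <- exp(-gamma * D2)
  diag(K) <- 1
  rn <- rownames(profiles)
  if (!is.null(rn)) dimnames(K) <- list(rn, rn)
  attr_k <- similarity_matrix(K, kind)
  attr(attr_k, "gamma") <- gamma
  attr_k
}

.check_aligned <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(dim(m), dim(mats[[1L]])) ||
        !identical(rownames(m), ids)) {
      stop("similarity matrices are not aligned (shape or id order differ)")
    }
  }
  invisible(TRUE)
}

#' Integrated miRNA similarity
#'
#' Element-wise weighted mean of the sequence, functional and GIPK
#' similarity matrices; all three weights default to 1.
#'
#' @param seq,func,gipk_m aligned `similarity_matrix` objects.
#' @param weights positive weights (alpha1, alpha2, alpha3).
#' @return `similarity_matrix` of kind `integrated_m`.
#' @export
integrate_mirna_similarity <- function(seq, func, gipk_m,
                                       weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights > 0))
  .check_aligned(seq, func, gipk_m)
  MS <- (weights[1] * unclass(seq) + weights[2] * unclass(func) +
           weights[3] * unclass(gipk_m)) / sum(weights)
  similarity_matrix(MS, "integrated_m")
}

#' Integrated abiotic-stress similarity
#'
#' Element-wise weighted mean of the semantic and GIPK stress similarity
#' matrices; both weights default to 1.
#'
#' @param sem,gipk_s aligned `similarity_matrix` objects.
#' @param weights positive weights (beta1, beta2).
#' @return `similarity_matrix` of kind `integrated_s`.
#' @export
integrate_stress_similarity <- function(sem, gipk_s, weights = c(1, 1)) {
  stopifnot(length(weights) == 2L, all(weights > 0))
  .check_aligned(sem, gipk_s)
  SS <- (weights[1] * unclass(sem) + weights[2] * unclass(gipk_s)) /
    sum(weights)
  similarity_matrix(SS, "integrated_s")
}
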
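#' Build the miRNA-abiotic-stress heterogeneous network
#'
#' Assembles the block matrix `H = [[MS, A], [A^T, SS]]` with miRNA nodes
#' first and stress nodes second. Negative similarity entries (possible
#' with cosine/Pearson channels) are clamped to 0 so the network supports
#' a probabilistic random walk; the number of clamped cells is recorded.
#'
#' @param MS integrated miRNA `similarity_matrix` (m x m).
#' @param SS integrated stress `similarity_matrix` (n x n).
#' @param A binary association matrix (m x n).
#' @return a `het_network`: list with `H`, `node_order`, `m`, `n`,
#'   `clamped` (count of negative cells set to 0).
#' @export
build_heterogeneous_network <- function(MS, SS, A) {
  m <- nrow(MS); n <- nrow(SS)
  if (ncol(MS) != m || ncol(SS) != n || nrow(A) != m || ncol(A) != n) {
    stop("dimension mismatch: MS must be m x m, SS n x n, A m x n")
  }
  if (!is.null(rownames(A)) && !is.null(rownames(MS)) &&
      !identical(rownames(A), rownames(MS))) {
    stop("miRNA id order of A and MS differ")
  }
  if (!is.null(colnames(A)) && !is.null(rownames(SS)) &&
      !identical(colnames(A), rownames(SS))) {
    stop("stress id order of A and SS differ")
  }
  H <- rbind(cbind(unclass(MS), A), cbind(t(A), unclass(SS)))
  clamped <- sum(H < 0)
  H[H < 0] <- 0
  node_order <- c(rownames(MS), rownames(SS))
  if (!is.null(node_order) && length(node_order) == m + n) {
    dimnames(H) <- list(node_order, node_order)
  } else {
    node_order <- c(paste0("m", seq_len(m)), paste0("s", seq_len(n)))
    dimnames(H) <- list(node_order, node_order)
  }
  stopifnot(max(abs(H - t(H))) <= 1e-10)
  structure(list(H = H, node_order = node_order, m = m, n = n,
                 clamped = clamped),
            class = "het_network")
}

#' @export
print.het_network <- function(x, ...) {
  cat("het_network:", x$m, "miRNAs +", x$n, "stresses;",
      x$clamped, "negative cells clamped\n")
  invisible(x)
}

#' Column-stochastic transition matrix of a network
#'
#' @param H non-negative square matrix (or a `het_network`).
#' @return matrix `T` with `T[, v] = H[, v] / colSums(H)[v]`; every
#'   column sums to 1.
#' @export
transition_matrix <- function(H) {
  if (inherits(H, "het_network")) H <- H$H
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  if (any(H < 0)) stop("H must be non-negative")
  cs <- colSums(H)
  if (any(cs == 0)) {
    ids <- colnames(H)
    bad <- if (is.null(ids)) which(cs == 0) else ids[cs == 0]
    stop("isolated node(s) with zero column sum: ",
         paste(bad, collapse = ", "))
  }
  sweep(H, 2L, cs, "/")
}

#' Random walk with restart: steady-state node features
#'
#' For every node v, iterates `p <- (1 - alpha) * T p + alpha * e_v` from
#' the one-hot start until the L1 change drops below `tol`. All walks are
#' iterated simultaneously as matrix columns. Row v of the returned
#' feature matrix is the steady-state distribution of the walk restarting
#' at v.
#'
#' @param H `het_network` or non-negative square matrix.
#' @param restart_prob restart probability alpha (default 0.7).
#' @param tol L1 convergence tolerance per walk (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return a `node_features` object: list with `P` ((m+n) x (m+n) matrix,
#'   rows are probability vectors), `restart_prob`, `tol`, `iterations`.
#' @export
rwr_steady_state <- function(H, restart_prob = 0.7, tol = 1e-6,
                             max_iter = 1000L) {
  stopifnot(restart_prob > 0, restart_prob <= 1)
  Tm <- transition_matrix(H)
  N <- nrow(Tm)
  P0 <- diag(N)
  P <- P0
  it <- 0L
  repeat {
    it <- it + 1L
    Pn <- (1 - restart_prob) * (Tm %*% P) + restart_prob * P0
    delta <- max(colSums(abs(Pn - P)))
    P <- Pn
    if (delta < tol) break
    if (it >= max_iter) {
      stop("RWR did not converge in ", max_iter,
           " iterations; worst L1 residual = ", format(delta))
    }
  }
  feats <- t(P)                      # row v = walk restarting at v
  dimnames(feats) <- dimnames(Tm)
  structure(list(P = feats, restart_prob = restart_prob, tol = tol,
                 iterations = it),
            class = "node_features")
}

#' Closed-form RWR steady state
#'
#' Solves the fixed point `p = (1 - alpha) T p + alpha e_v` directly as
#' `p = alpha (I - (1 - alpha) T)^{-1} e_v` for all nodes at once; used
#' to validate the iterative solver.
#'
#' @inheritParams rwr_steady_state
#' @return matrix with row v = steady state of the walk restarting at v.
#' @export
rwr_closed_form <- function(H, restart_prob = 0.7) {
  Tm <- transition_matrix(H)
  N <- nrow(Tm)
  P <- restart_prob * solve(diag(N) - (1 - restart_prob) * Tm)
  feats <- t(P)
  dimnames(feats) <- dimnames(Tm)
  feats
}

#' @export
print.node_features <- function(x, ...) {
  cat("node_features:", nrow(x$P), "nodes; restart =", x$restart_prob,
      "; converged in", x$iterations, "iterations\n")
  invisible(x)
}
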
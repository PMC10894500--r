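# Graph autoencoder with a Graph Isomorphism Network (GIN) encoder and an
# inner-product sigmoid decoder. Each GIN layer computes
#   h_v' = MLP((1 + eps) h_v + agg_{u} W[v,u] h_u)
# with a learnable eps and a two-linear-layer MLP (ReLU in between); the
# "sum" aggregator uses the weighted neighbor sum, the "mean" aggregator
# divides it by the node's weighted degree. The decoder reconstructs the
# adjacency as sigmoid(Z Z^T) and the model is trained with Adam on the
# mean binary cross-entropy over labelled miRNA x stress cells.
# Gradients are computed in closed form (no autodiff dependency) and are
# verified against numerical differentiation in the test suite.

#' Encoder configuration
#'
#' @param n_layers number of GIN layers (1..4; default 2).
#' @param hidden_dims output dimension of each layer (default c(256, 128)).
#' @param aggregators per-layer neighbor aggregation, "mean" or "sum"
#'   (default c("mean", "sum"), the best-performing combination).
#' @param dropout dropout rate on MLP hidden activations (default 0).
#' @param mlp_hidden per-layer MLP hidden width; defaults to the layer's
#'   output dimension.
#' @param eps_init initial value of each layer's learnable eps.
#' @param seed RNG seed for weight initialization (and dropout).
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 2L, hidden_dims = c(256L, 128L),
                           aggregators = c("mean", "sum"), dropout = 0,
                           mlp_hidden = NULL, eps_init = 0, seed = 1L) {
  stopifnot(n_layers >= 1L, n_layers <= 4L,
            length(hidden_dims) == n_layers,
            all(hidden_dims > 0),
            length(aggregators) == n_layers,
            all(aggregators %in% c("mean", "sum")),
            dropout >= 0, dropout < 1)
  if (is.null(mlp_hidden)) mlp_hidden <- hidden_dims
  stopifnot(length(mlp_hidden) == n_layers, all(mlp_hidden > 0))
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dims = as.integer(hidden_dims),
                 aggregators = aggregators, dropout = dropout,
                 mlp_hidden = as.integer(mlp_hidden),
                 eps_init = eps_init, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param epochs training epochs (default 200).
#' @param negative_ratio sampled negatives per positive (default 1).
#' @param seed RNG seed for negative sampling.
#' @param loss_clip_eps probability clipping bound for the log loss.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 200L, negative_ratio = 1,
                         seed = 1L, loss_clip_eps = 1e-7) {
  stopifnot(lr > 0, epochs >= 1L, negative_ratio > 0, loss_clip_eps > 0)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 negative_ratio = negative_ratio, seed = as.integer(seed),
                 loss_clip_eps = loss_clip_eps),
            class = "train_config")
}

# Aggregation operator as a matrix: sum -> W itself, mean -> row-normalized
# W (rows with zero weighted degree stay zero).
.gin_agg_operator <- function(W, aggregator) {
  if (aggregator == "sum") return(W)
  rs <- rowSums(W)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W * scale
}

#' One GIN layer
#'
#' @param h node feature matrix (one row per node).
#' @param W non-negative weighted adjacency matrix.
#' @param eps scalar eps of the layer.
#' @param mlp function applied row-wise to the aggregated features
#'   (default identity).
#' @param aggregator "sum" (weighted neighbor sum) or "mean".
#' @return updated node feature matrix `mlp((1 + eps) h + agg)`.
#' @export
gin_layer <- function(h, W, eps = 0, mlp = identity,
                      aggregator = c("sum", "mean")) {
  aggregator <- match.arg(aggregator)
  stopifnot(is.matrix(h), is.matrix(W), nrow(W) == ncol(W),
            nrow(h) == nrow(W))
  if (any(W < 0)) stop("W must be non-negative")
  agg <- .gin_agg_operator(W, aggregator) %*% h
  mlp((1 + eps) * h + agg)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weight initialization, zero biases, eps at `eps_init`.
#'
#' @param config an `encoder_config`.
#' @param d_in input feature dimension.
#' @return list of per-layer parameter lists (A1, b1, A2, b2, eps).
#' @export
gae_init <- function(config, d_in) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  params <- vector("list", config$n_layers)
  din <- d_in
  for (k in seq_len(config$n_layers)) {
    hid <- config$mlp_hidden[k]
    dout <- config$hidden_dims[k]
    params[[k]] <- list(A1 = glorot(din, hid), b1 = numeric(hid),
                        A2 = glorot(hid, dout), b2 = numeric(dout),
                        eps = config$eps_init)
    din <- dout
  }
  params
}

# Forward pass keeping intermediates for backprop.
.gae_forward <- function(params, X, W, config, dropout_masks = NULL) {
  n_layers <- config$n_layers
  cache <- vector("list", n_layers)
  Hk <- X
  for (k in seq_len(n_layers)) {
    p <- params[[k]]
    Ak <- .gin_agg_operator(W, config$aggregators[k])
    S <- (1 + p$eps) * Hk + Ak %*% Hk
    U <- sweep(S %*% p$A1, 2L, p$b1, "+")
    R <- pmax(U, 0)
    if (!is.null(dropout_masks)) R <- R * dropout_masks[[k]]
    Hn <- sweep(R %*% p$A2, 2L, p$b2, "+")
    if (any(!is.finite(Hn))) stop("non-finite activations in layer ", k)
    cache[[k]] <- list(Hin = Hk, Agg = Ak, S = S, U = U, R = R)
    Hk <- Hn
  }
  list(Z = Hk, cache = cache)
}

#' Encode nodes with the GIN encoder
#'
#' @param X initial node feature matrix ((m+n) x d).
#' @param W non-negative weighted adjacency ((m+n) x (m+n)).
#' @param params parameters from [gae_init()] or a trained model.
#' @param config the matching `encoder_config`.
#' @return embedding matrix Z ((m+n) x last hidden dim).
#' @export
gae_encode <- function(X, W, params, config) {
  stopifnot(is.matrix(X), is.matrix(W), nrow(X) == nrow(W))
  .gae_forward(params, X, W, config)$Z
}

#' Decode embeddings to association scores
#'
#' @param Z embedding matrix ((m+n) x d), miRNA rows first.
#' @param m,n numbers of miRNA and stress nodes; when omitted only the
#'   full matrix is returned.
#' @return list with `full` = sigmoid(Z Z^T) and, when `m`/`n` are given,
#'   `scores` = its miRNA x stress block.
#' @export
gae_decode <- function(Z, m = NULL, n = NULL) {
  stopifnot(all(is.finite(Z)))
  logits <- Z %*% t(Z)
  full <- 1 / (1 + exp(-logits))
  out <- list(full = full)
  if (!is.null(m) && !is.null(n)) {
    stopifnot(m + n == nrow(Z))
    out$scores <- full[seq_len(m), m + seq_len(n), drop = FALSE]
    rn <- rownames(Z)
    if (!is.null(rn)) dimnames(out$scores) <- list(rn[seq_len(m)],
                                                   rn[m + seq_len(n)])
  }
  out
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log y' + (1 - y) log(1 - y'))` with scores clipped into
#' `[clip_eps, 1 - clip_eps]` to keep the logs finite.
#'
#' @param y 0/1 labels.
#' @param y_hat predicted probabilities.
#' @param clip_eps clipping bound (default 1e-7).
#' @return scalar loss.
#' @export
bce_loss <- function(y, y_hat, clip_eps = 1e-7) {
  if (length(y) != length(y_hat)) stop("label/score length mismatch")
  p <- pmin(pmax(y_hat, clip_eps), 1 - clip_eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Forward + loss + closed-form gradients for one full-batch step.
# ia/jb are global node indices of the scored (miRNA, stress) cells.
.gae_loss_grads <- function(params, X, W, config, ia, jb, y, clip_eps,
                            dropout_masks = NULL) {
  fw <- .gae_forward(params, X, W, config, dropout_masks)
  Z <- fw$Z
  L <- length(y)
  N <- nrow(Z)
  logits <- rowSums(Z[ia, , drop = FALSE] * Z[jb, , drop = FALSE])
  p <- 1 / (1 + exp(-logits))
  loss <- bce_loss(y, p, clip_eps)

  # dL/dlogit = (p - y)/L, pushed into the two embedding rows of each cell
  g <- (p - y) / L
  dZ <- matrix(0, N, ncol(Z))
  tmp_a <- rowsum(g * Z[jb, , drop = FALSE], ia)
  dZ[as.integer(rownames(tmp_a)), ] <-
    dZ[as.integer(rownames(tmp_a)), , drop = FALSE] + tmp_a
  tmp_b <- rowsum(g * Z[ia, , drop = FALSE], jb)
  dZ[as.integer(rownames(tmp_b)), ] <-
    dZ[as.integer(rownames(tmp_b)), , drop = FALSE] + tmp_b

  grads <- vector("list", config$n_layers)
  dH <- dZ
  for (k in rev(seq_len(config$n_layers))) {
    cc <- fw$cache[[k]]
    pk <- params[[k]]
    db2 <- colSums(dH)
    dA2 <- crossprod(cc$R, dH)
    dR <- dH %*% t(pk$A2)
    if (!is.null(dropout_masks)) dR <- dR * dropout_masks[[k]]
    dU <- dR * (cc$U > 0)
    db1 <- colSums(dU)
    dA1 <- crossprod(cc$S, dU)
    dS <- dU %*% t(pk$A1)
    deps <- sum(dS * cc$Hin)
    dH <- (1 + pk$eps) * dS + crossprod(cc$Agg, dS)
    grads[[k]] <- list(A1 = dA1, b1 = db1, A2 = dA2, b2 = db2, eps = deps)
  }
  list(loss = loss, grads = grads, Z = Z)
}

#' Train the GIN graph autoencoder
#'
#' Minimizes the mean binary cross-entropy over the supplied labelled
#' miRNA x stress cells with Adam. Labels normally hold the training
#' positives plus an equal number of sampled negatives (see
#' [kfold_splits()]); the loss is never taken over the full (m+n)^2
#' reconstruction.
#'
#' @param X initial node features ((m+n) x d), e.g. the RWR steady-state
#'   matrix.
#' @param W message-passing weights, normally the heterogeneous network H.
#' @param cells integer matrix (L x 2) of (miRNA row, stress column)
#'   indices into the association block.
#' @param y 0/1 labels for `cells`.
#' @param m,n numbers of miRNA and stress nodes.
#' @param config an `encoder_config`.
#' @param train an `train_config`.
#' @return a `gae_model`: list with `params`, `config`, `train`,
#'   `loss_trace`, `Z`, `scores` (m x n predicted probabilities), `full`.
#' @export
train_gae <- function(X, W, cells, y, m, n,
                      config = encoder_config(),
                      train = train_config()) {
  stopifnot(nrow(X) == m + n, nrow(W) == m + n, is.matrix(cells),
            ncol(cells) == 2L, length(y) == nrow(cells),
            all(y %in% c(0, 1)),
            all(cells[, 1L] >= 1L), all(cells[, 1L] <= m),
            all(cells[, 2L] >= 1L), all(cells[, 2L] <= n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  params <- gae_init(config, ncol(X))
  adam <- lapply(params, function(p) list(
    m = lapply(p[c("A1", "b1", "A2", "b2", "eps")], function(x) x * 0),
    v = lapply(p[c("A1", "b1", "A2", "b2", "eps")], function(x) x * 0)))
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8

  ia <- cells[, 1L]                 # miRNA node index
  jb <- m + cells[, 2L]             # global stress node index
  loss_trace <- numeric(train$epochs)
  N <- m + n

  for (ep in seq_len(train$epochs)) {
    masks <- NULL
    if (config$dropout > 0) {
      keep <- 1 - config$dropout
      masks <- lapply(seq_len(config$n_layers), function(k) {
        dims <- c(N, config$mlp_hidden[k])
        matrix(stats::rbinom(prod(dims), 1L, keep) / keep, dims[1], dims[2])
      })
    }
    step <- .gae_loss_grads(params, X, W, config, ia, jb, y,
                            train$loss_clip_eps, masks)
    if (!is.finite(step$loss)) stop("loss diverged (NaN/Inf) at epoch ", ep)
    loss_trace[ep] <- step$loss
    grads <- step$grads

    corr <- sqrt(1 - b2^ep) / (1 - b1^ep)
    for (k in seq_len(config$n_layers)) {
      for (nm in c("A1", "b1", "A2", "b2", "eps")) {
        gk <- grads[[k]][[nm]]
        adam[[k]]$m[[nm]] <- b1 * adam[[k]]$m[[nm]] + (1 - b1) * gk
        adam[[k]]$v[[nm]] <- b2 * adam[[k]]$v[[nm]] + (1 - b2) * gk^2
        params[[k]][[nm]] <- params[[k]][[nm]] -
          train$lr * corr * adam[[k]]$m[[nm]] /
          (sqrt(adam[[k]]$v[[nm]]) + aeps)
      }
    }
  }

  Z <- .gae_forward(params, X, W, config)$Z
  rownames(Z) <- rownames(W)
  dec <- gae_decode(Z, m, n)
  structure(list(params = params, config = config, train = train,
                 loss_trace = loss_trace, Z = Z,
                 scores = dec$scores, full = dec$full),
            class = "gae_model")
}

#' @export
print.gae_model <- function(x, ...) {
  cat("gae_model:", x$config$n_layers, "GIN layer(s), dims",
      paste(x$config$hidden_dims, collapse = "-"),
      "; final loss", format(utils::tail(x$loss_trace, 1), digits = 4), "\n")
  invisible(x)
}
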
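test_that("gin_layer matches hand-computed path-graph cases", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  h <- matrix(c(1, 0, 2, 1, 3, 5), 3, 2)

  out_sum <- gin_layer(h, W, eps = 0, aggregator = "sum")
  expect_equal(out_sum[2, ], h[2, ] + h[1, ] + h[3, ])
  out_mean <- gin_layer(h, W, eps = 0, aggregator = "mean")
  expect_equal(out_mean[2, ], h[2, ] + (h[1, ] + h[3, ]) / 2)

  # isolated node passes through unchanged with identity MLP
  W0 <- matrix(0, 2, 2); h0 <- matrix(c(3, 1, 4, 1), 2, 2)
  expect_equal(gin_layer(h0, W0, aggregator = "sum"), h0)
  expect_equal(gin_layer(h0, W0, aggregator = "mean"), h0)

  # eps scales the self contribution
  expect_equal(gin_layer(h0, W0, eps = 0.5, aggregator = "sum"), 1.5 * h0)
})

test_that("vectorized encoder equals a per-node loop on random graphs", {
  set.seed(55)
  for (rep in 1:5) {
    W <- matrix(runif(100), 10, 10); W <- (W + t(W)) / 2
    h <- matrix(rnorm(40), 10, 4)
    cfg <- encoder_config(n_layers = 2L, hidden_dims = c(6L, 3L),
                          aggregators = c("mean", "sum"), seed = rep)
    params <- gae_init(cfg, 4L)
    Z <- gae_encode(h, W, params, cfg)

    mlp_of <- function(p) function(x)
      sweep(pmax(sweep(x %*% p$A1, 2, p$b1, "+"), 0) %*% p$A2, 2, p$b2, "+")
    h1 <- brute_gin_layer(h, W, params[[1]]$eps, mlp_of(params[[1]]), "mean")
    h2 <- brute_gin_layer(h1, W, params[[2]]$eps, mlp_of(params[[2]]), "sum")
    expect_lt(max(abs(Z - h2)), 1e-6)
  }
})

test_that("encoding is deterministic under a fixed seed", {
  set.seed(1); W <- matrix(runif(36), 6, 6); W <- (W + t(W)) / 2
  X <- matrix(rnorm(24), 6, 4)
  cfg <- encoder_config(hidden_dims = c(5L, 3L), seed = 42)
  Z1 <- gae_encode(X, W, gae_init(cfg, 4L), cfg)
  Z2 <- gae_encode(X, W, gae_init(cfg, 4L), cfg)
  expect_identical(Z1, Z2)
})

test_that("decoder is a symmetric sigmoid inner product", {
  Z0 <- matrix(0, 4, 3)
  expect_equal(gae_decode(Z0)$full, matrix(0.5, 4, 4))
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  full <- gae_decode(Z)$full
  expect_equal(full, t(full))
  expect_equal(full[1, 2], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_true(all(full > 0 & full < 1))
  dec <- gae_decode(Z, m = 2, n = 1)
  expect_equal(dim(dec$scores), c(2L, 1L))
  expect_equal(dec$scores[1, 1], full[1, 3])
})

test_that("binary cross-entropy matches its closed form", {
  expect_equal(bce_loss(1, 0.5), -log(0.5), tolerance = 1e-12)
  eps <- 1e-7
  expect_lt(bce_loss(c(0, 1), c(eps, 1 - eps)), 1e-6)
  y <- c(1, 0, 1, 0); p <- c(0.9, 0.2, 0.6, 0.4)
  per <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce_loss(y, p), mean(per), tolerance = 1e-12)
  expect_error(bce_loss(c(1, 0), 0.5), "length")
  expect_gte(bce_loss(c(1, 0), c(0.3, 0.8)), 0)
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(9)
  N <- 6L; m <- 4L; n <- 2L
  W <- matrix(runif(N * N), N, N); W <- (W + t(W)) / 2
  X <- matrix(rnorm(N * 3), N, 3)
  cfg <- encoder_config(n_layers = 2L, hidden_dims = c(4L, 3L),
                        aggregators = c("mean", "sum"), seed = 3)
  params <- gae_init(cfg, 3L)
  cells <- cbind(c(1, 2, 3, 4), c(1, 2, 1, 2))
  y <- c(1, 0, 1, 0)
  ia <- cells[, 1]; jb <- m + cells[, 2]

  res <- mirstress:::.gae_loss_grads(params, X, W, cfg, ia, jb, y, 1e-7)
  loss_at <- function(pp)
    mirstress:::.gae_loss_grads(pp, X, W, cfg, ia, jb, y, 1e-7)$loss
  hstep <- 1e-6
  for (k in 1:2) {
    for (nm in c("A1", "b1", "A2", "b2", "eps")) {
      val <- params[[k]][[nm]]
      idx <- if (length(val) > 3) sample(length(val), 3) else seq_along(val)
      for (i in idx) {
        pp <- params
        pp[[k]][[nm]][i] <- val[i] + hstep
        up <- loss_at(pp)
        pp[[k]][[nm]][i] <- val[i] - hstep
        dn <- loss_at(pp)
        expect_equal(res$grads[[k]][[nm]][i], (up - dn) / (2 * hstep),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and fits planted structure", {
  gen <- generate_synthetic_dataset(synthetic_spec(n_mirna = 40L,
                                                   n_stress = 6L,
                                                   n_blocks = 2L, seed = 4))
  ds <- gen$dataset
  m <- nrow(ds$A); n <- ncol(ds$A)
  MS <- similarity_matrix(diag(m) * 0 + diag(m), "integrated_m")
  dimnames(MS) <- list(ds$mirna_ids, ds$mirna_ids)
  SS <- similarity_matrix(diag(n), "integrated_s")
  dimnames(SS) <- list(ds$stress_terms, ds$stress_terms)
  net <- build_heterogeneous_network(MS, SS, ds$A)
  Xf <- rwr_steady_state(net)$P

  pos <- which(ds$A == 1, arr.ind = TRUE)
  set.seed(5)
  zeros <- which(ds$A == 0)
  neg <- zeros[sample(length(zeros), nrow(pos))]
  cells <- rbind(pos, cbind((neg - 1) %% m + 1, (neg - 1) %/% m + 1))
  y <- c(rep(1, nrow(pos)), rep(0, nrow(pos)))
  cfg <- encoder_config(hidden_dims = c(32L, 16L), seed = 6)
  model <- train_gae(Xf, net$H, cells, y, m, n, config = cfg,
                     train = train_config(epochs = 200L))
  expect_lt(tail(model$loss_trace, 1), model$loss_trace[1])
  # sigmoid output; confident logits may saturate to 1 in double precision
  expect_true(all(model$scores >= 0 & model$scores <= 1))
  # held-in fit: the reconstruction separates train labels well
  expect_gte(compute_metrics(y, model$scores[cells])$auc, 0.95)

  # determinism under fixed seeds
  model2 <- train_gae(Xf, net$H, cells, y, m, n, config = cfg,
                      train = train_config(epochs = 5L))
  model3 <- train_gae(Xf, net$H, cells, y, m, n, config = cfg,
                      train = train_config(epochs = 5L))
  expect_identical(model2$scores, model3$scores)
})
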
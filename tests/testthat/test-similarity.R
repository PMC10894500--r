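test_that("cosine semantic similarity matches hand-computed values", {
  vecs <- rbind(cold = c(1, 0), drought = c(1, 1), heat = c(0, 1),
                salt = c(2, 0))
  tab <- structure(list(dim = 2L, vectors = vecs, seed = 1L),
                   class = "embedding_table")
  rec <- data.frame(mirna = paste0("m", 1:4),
                    stress = c("cold", "drought", "heat", "salt"),
                    sequence = random_rna(4, seed = 2))
  ds <- build_association_dataset(rec)
  S <- semantic_similarity(ds, tab)
  expect_equal(S["cold", "cold"], 1)
  expect_equal(S["cold", "heat"], 0)
  expect_equal(S["cold", "drought"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(S["cold", "salt"], 1)               # scale invariance
  expect_true(all(S >= -1 & S <= 1))
})

test_that("stress-set similarity is the best-match maximum", {
  sem <- similarity_matrix(
    matrix(c(1, 0.2, 0.9, 0.4,
             0.2, 1, 0.5, 0.1,
             0.9, 0.5, 1, 0.3,
             0.4, 0.1, 0.3, 1), 4, 4,
           dimnames = list(letters[1:4], letters[1:4])), "sem")
  expect_equal(stress_set_similarity(1, 2:4, sem), 0.9)
  expect_equal(stress_set_similarity(2, c(1, 2, 3), sem), 1)  # self in set
  expect_equal(stress_set_similarity(1, integer(0), sem), 0)
})

test_that("functional similarity matches the worked case and brute force", {
  # worked case: ST1 = {s1}, ST2 = {s2, s3}, sem(s1,s2)=0.8, sem(s1,s3)=0.2
  sem <- similarity_matrix(
    matrix(c(1, 0.8, 0.2,
             0.8, 1, 0.5,
             0.2, 0.5, 1), 3, 3,
           dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))), "sem")
  A <- matrix(c(1L, 0L, 0L, 0L, 1L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  ds <- list(mirna_ids = c("m1", "m2"), stress_terms = c("s1", "s2", "s3"),
             A = A)
  Fm <- functional_similarity(ds, sem)
  expect_equal(Fm["m1", "m2"], 0.6, tolerance = 1e-12)
  expect_equal(diag(unclass(Fm)), c(m1 = 1, m2 = 1))

  # identical singleton sets -> 1; disjoint with zero cross-sim -> 0
  sem0 <- similarity_matrix(diag(2), "sem")
  dimnames(sem0) <- list(c("x", "y"), c("x", "y"))
  A1 <- matrix(c(1L, 1L, 0L, 0L), 2, 2,
               dimnames = list(c("m1", "m2"), c("x", "y")))
  F1 <- functional_similarity(list(mirna_ids = c("m1", "m2"),
                                   stress_terms = c("x", "y"), A = A1), sem0)
  expect_equal(F1["m1", "m2"], 1)
  A2 <- diag(2L); dimnames(A2) <- dimnames(A1)
  F2 <- functional_similarity(list(mirna_ids = c("m1", "m2"),
                                   stress_terms = c("x", "y"), A = A2), sem0)
  expect_equal(F2["m1", "m2"], 0)

  # brute-force oracle on random instances
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(3:8, 1); n <- sample(2:5, 1)
    A <- matrix(rbinom(m * n, 1L, 0.4), m, n)
    sem_r <- random_sim(n, seed = seed)
    ds_r <- list(mirna_ids = sprintf("m%d", 1:m),
                 stress_terms = rownames(sem_r), A = A)
    got <- functional_similarity(ds_r, sem_r)
    want <- brute_func(A, unclass(sem_r)); diag(want) <- 1
    expect_lt(max(abs(unclass(got) - want)), 1e-12)
  }
})

test_that("sequence similarity is Pearson correlation of CGR features", {
  rec <- data.frame(mirna = c("m1", "m2", "m3"),
                    stress = c("s", "s", "s"),
                    sequence = c("ACGUACGUACGUACGUACGUAC",
                                 "ACGUACGUACGUACGUACGUAC",
                                 random_rna(1, 22, seed = 8)))
  ds <- build_association_dataset(rec)
  S <- sequence_similarity(ds)
  expect_equal(S["m1", "m2"], 1)            # identical sequences
  expect_equal(diag(unclass(S)), setNames(rep(1, 3), ds$mirna_ids))
  expect_true(all(S >= -1 & S <= 1))

  # oracle equivalence: plain cor() of independently recomputed features
  f <- vapply(ds$mirna_ids, function(id)
    cgr_feature_vector(cgr_trajectory(ds$sequences[[id]]), 8)$vector,
    numeric(3 * 64))
  expect_lt(max(abs(unclass(S) - stats::cor(f))), 1e-12)
})

test_that("GIPK matches the hand case and a brute-force double loop", {
  K <- gipk_matrix(diag(2), "gipk_m")
  expect_equal(K[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(attr(K, "gamma"), 1)
  expect_equal(diag(unclass(K)), c(1, 1), ignore_attr = TRUE)

  set.seed(17)
  for (rep in 1:50) {
    P <- matrix(rbinom(24, 1L, 0.5), 6, 4)
    if (sum(P) == 0) next
    got <- unclass(gipk_matrix(P, "gipk_m"))
    expect_lt(max(abs(got - brute_gipk(P))), 1e-12)
  }
  expect_true(all(unclass(gipk_matrix(matrix(c(1, 0, 0, 1), 2))) > 0))
  expect_error(gipk_matrix(matrix(0, 3, 3)), "all-zero")
})

test_that("similarity integration takes element-wise weighted means", {
  M <- random_sim(4, seed = 1, kind = "seq")
  expect_equal(unclass(integrate_mirna_similarity(M, similarity_matrix(unclass(M), "func"),
                                                  similarity_matrix(unclass(M), "gipk_m"))),
               unclass(M), ignore_attr = TRUE)
  a <- similarity_matrix(matrix(0.9, 1, 1, dimnames = list("x", "x")), "seq")
  b <- similarity_matrix(matrix(0.6, 1, 1, dimnames = list("x", "x")), "func")
  c_ <- similarity_matrix(matrix(0.3, 1, 1, dimnames = list("x", "x")), "gipk_m")
  expect_equal(as.numeric(integrate_mirna_similarity(a, b, c_)), 0.6)
  expect_equal(as.numeric(integrate_mirna_similarity(a, b, c_,
                                                     weights = c(2, 1, 1))),
               0.675)
  d <- similarity_matrix(matrix(0.5, 1, 1, dimnames = list("x", "x")), "sem")
  e <- similarity_matrix(matrix(0.9, 1, 1, dimnames = list("x", "x")), "gipk_s")
  expect_equal(as.numeric(integrate_stress_similarity(d, e)), 0.7)
  expect_equal(as.numeric(integrate_stress_similarity(d, e, weights = c(3, 1))),
               0.6)
  wrong <- random_sim(3, seed = 2, kind = "func")
  expect_error(integrate_mirna_similarity(M, wrong, wrong), "aligned")
})

test_that("similarity matrices are symmetric and relabeling-invariant", {
  ds <- random_dataset(7, 4, seed = 21)
  sem <- random_sim(4, seed = 3, ids = ds$stress_terms)
  for (S in list(functional_similarity(ds, sem),
                 sequence_similarity(ds),
                 gipk_matrix(ds$A, "gipk_m"))) {
    expect_lt(max(abs(unclass(S) - t(unclass(S)))), 1e-10)
  }

  # renaming ids consistently permutes but does not change values
  perm <- c(3, 1, 2, 4, 6, 5, 7)
  ds2 <- list(mirna_ids = ds$mirna_ids[perm],
              stress_terms = ds$stress_terms,
              sequences = ds$sequences[perm],
              A = ds$A[perm, ])
  F1 <- unclass(functional_similarity(ds, sem))
  F2 <- unclass(functional_similarity(ds2, sem))
  expect_equal(F2, F1[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})
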
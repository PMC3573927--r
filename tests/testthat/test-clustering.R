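test_that("adjacency model satisfies its structural invariants", {
  sim <- simulate_scenario(scenario_spec(1, T = 60), seed = 1)
  adj <- build_adjacency(sim$tsm)
  W <- adj$W
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(0, nrow(W)))
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(adj$L, diag(adj$d) - W)
  expect_true(all(adj$d >= 0 & adj$d <= 1))
  adj2 <- build_adjacency(sim$tsm, degree_mode = "row_sum")
  expect_equal(adj2$d, rowSums(W))
})

test_that("within-module similarity exceeds between-module similarity", {
  spec <- scenario_spec(1, T = 200)
  ok <- sapply(1:10, function(i) {
    sim <- simulate_scenario(spec, seed = 500 + i)
    W <- build_adjacency(sim$tsm, degree_mode = "row_sum")$W
    same <- outer(sim$true_labels, sim$true_labels, "==")
    diag(same) <- NA
    mean(W[which(same)]) > mean(W[which(!same)])
  })
  expect_true(all(ok))
})

test_that("spectral embedding returns orthonormal, correctly ordered eigenpairs", {
  sim <- simulate_scenario(scenario_spec(1, T = 60), seed = 2)
  adj <- build_adjacency(sim$tsm)
  emb <- spectral_embed(adj, 4)
  expect_equal(crossprod(emb$U), diag(4), tolerance = 1e-8)
  expect_true(all(diff(emb$eigenvalues) >= -1e-10))   # ascending (smallest)
  for (j in 1:4)
    expect_lt(max(abs(adj$L %*% emb$U[, j] - emb$eigenvalues[j] * emb$U[, j])),
              1e-8)
  embL <- spectral_embed(adj, 3, eig_order = "largest")
  expect_true(all(diff(embL$eigenvalues) <= 1e-10))   # descending
  expect_error(spectral_embed(adj, nrow(adj$W) + 1), "k must be")
})

test_that("two disconnected 2-cliques have the closed-form Laplacian spectrum", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
  adj <- structure(list(W = W, d = rowSums(W), L = diag(rowSums(W)) - W,
                        degree_mode = "row_sum", series_ids = paste0("s", 1:4)),
                   class = "gc_adjacency")
  emb <- spectral_embed(adj, 4)
  expect_equal(sort(emb$eigenvalues), c(0, 0, 2, 2), tolerance = 1e-12)
  # the two null-space eigenvectors separate the cliques
  cl <- kmeans_embed(spectral_embed(adj, 2), 2, seed = 1)
  expect_equal(clustering_accuracy(cl$labels, c(1, 1, 2, 2)), 100)
})

test_that("k-means embedding is seeded, optimal on small cases, and separable", {
  set.seed(3)
  U <- rbind(matrix(rnorm(10, mean = 0, sd = 0.05), 5, 2),
             matrix(rnorm(10, mean = 3, sd = 0.05), 5, 2))
  emb <- structure(list(U = U, eigenvalues = rep(0, 2), eig_order = "smallest"),
                   class = "spectral_embedding")
  cl <- kmeans_embed(emb, 2, seed = 4)
  expect_equal(clustering_accuracy(cl$labels, rep(1:2, each = 5)), 100)
  expect_identical(kmeans_embed(emb, 2, seed = 9)$labels,
                   kmeans_embed(emb, 2, seed = 9)$labels)

  U8 <- matrix(rnorm(16), 8, 2)
  emb8 <- structure(list(U = U8, eigenvalues = rep(0, 2), eig_order = "smallest"),
                    class = "spectral_embedding")
  got <- kmeans_embed(emb8, 2, n_init = 200, seed = 5)
  oracle <- oracle_best_bipartition(U8)
  expect_equal(got$inertia, oracle$wss, tolerance = 1e-8)
  expect_equal(clustering_accuracy(got$labels, oracle$labels), 100)
})

test_that("functional clustering recovers block structure and is equivariant", {
  spec <- scenario_spec(1, T = 200)
  sim <- simulate_scenario(spec, seed = 6)
  cl <- functional_cluster(sim$tsm, 4, seed = 6)
  expect_gte(clustering_accuracy(cl$labels, sim$true_labels), 99)

  # row permutation permutes the labels identically (up to renumbering)
  perm <- sample(sim$tsm$p)
  tsm_p <- ts_matrix(sim$tsm$values[perm, ], sim$tsm$series_ids[perm])
  cl_p <- functional_cluster(tsm_p, 4, seed = 6)
  expect_equal(clustering_accuracy(cl_p$labels, cl$labels[perm]), 100)

  # per-series affine rescaling leaves the partition unchanged
  sc <- ts_matrix(sim$tsm$values * runif(sim$tsm$p, 0.5, 3) +
                    rnorm(sim$tsm$p), sim$tsm$series_ids)
  cl_s <- functional_cluster(sc, 4, seed = 6)
  expect_equal(clustering_accuracy(cl_s$labels, cl$labels), 100)
})

test_that("a block-diagonal similarity graph is recovered exactly", {
  two <- sim_two_modules(p = 12, T_len = 150, seed = 7)
  cl <- functional_cluster(ts_matrix(two$X), 2, seed = 7)
  expect_equal(clustering_accuracy(cl$labels, two$labels), 100)
})
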
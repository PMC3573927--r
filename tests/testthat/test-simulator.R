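# independent transcription of the latent equation systems: one line per
# equation, "target: signed sources", beta terms as bare numbers, gamma terms
# prefixed with g
.eqs_scenario1 <- c(
  "1: +1 -4 +3",  "2: +1 -3 +4",  "3: +1 -5",     "4: +3 -5",
  "5: +2 -3 +4",  "6: +9 -7",     "7: +10 -7",    "8: +10 -6 +7",
  "9: +7 -8 +9 -6", "10: +10 -6 +9", "11: +12 -15", "12: +14 -13",
  "13: +14 -11",  "14: +13 -11",  "15: +15 -12 +13 -14",
  "16: +19 -20 +17 -18", "17: +20 -17 +18", "18: +20 -18",
  "19: +17 -18",  "20: +20 -19")

.parse_eqs <- function(lines, beta = 0.6, gamma = 0.3) {
  A <- matrix(0, 20, 20)
  for (ln in lines) {
    parts <- strsplit(ln, ":")[[1]]
    i <- as.integer(parts[1])
    for (term in strsplit(trimws(parts[2]), " +")[[1]]) {
      w <- if (grepl("g", term, fixed = TRUE)) gamma else beta
      j <- as.integer(gsub("[^0-9]", "", term))
      A[i, j] <- A[i, j] + if (startsWith(term, "-")) -w else w
    }
  }
  A
}

test_that("preset coefficient matrices match an independent parse", {
  spec1 <- scenario_spec(1)
  expect_equal(spec1$latent, .parse_eqs(.eqs_scenario1))
  # 52 signed beta terms in scenario 1
  expect_equal(sum(spec1$latent != 0), 52L)

  # scenario 2 is scenario 1 plus the four cycle couplings
  spec2 <- scenario_spec(2)
  extra <- spec2$latent - spec1$latent
  expect_equal(sum(extra != 0), 4L)
  expect_equal(extra[3, 19], 0.3)   # D -> A
  expect_equal(extra[6, 3], 0.3)    # A -> B
  expect_equal(extra[14, 10], 0.3)  # B -> C
  expect_equal(extra[20, 15], 0.3)  # C -> D

  # gamma = 0 collapses scenario 2 onto scenario 1
  expect_equal(scenario_spec(2, gamma = 0)$latent, spec1$latent)

  # scenario 3 carries the feedback loop A <-> B
  spec3 <- scenario_spec(3)
  expect_equal(spec3$latent[3, 6] - spec1$latent[3, 6], 0.3)
  expect_equal(spec3$latent[7, 3] - spec1$latent[7, 3], 0.3)

  # scenario 4: A sends to B and C, D only receives
  spec4 <- scenario_spec(4)
  d4 <- spec4$latent - spec1$latent
  expect_equal(d4[7, 3], 0.3); expect_equal(d4[13, 8], 0.3)
  expect_equal(d4[14, 5], 0.3); expect_equal(d4[20, 15], 0.3)
  expect_equal(sum(d4 != 0), 4L)
})

test_that("replicate expansion applies coefficients replicate-wise", {
  spec <- scenario_spec(1, n_replicates = 10)
  A <- build_coefficient_matrix(spec)
  expect_equal(dim(A), c(200L, 200L))
  # replicate r of a target depends only on replicate r of each source
  expect_equal(A[1, 1], 0.6)           # A1.r1 on its own lag
  expect_equal(A[1, 2], 0)             # not on A1.r2
  expect_equal(A[2, 2], 0.6)
  expect_equal(A[1, 31], -0.6)         # A1.r1 on A4.r1 (rows 31-40 = latent 4)
  expect_equal(sum(A != 0), 52L * 10L)
})

test_that("simulation output is reproducible with the expected structure", {
  spec <- scenario_spec(1, T = 50)
  s1 <- simulate_scenario(spec, seed = 42)
  s2 <- simulate_scenario(spec, seed = 42)
  expect_equal(s1$tsm$values, s2$tsm$values)
  expect_equal(dim(s1$tsm$values), c(200L, 50L))
  expect_equal(unname(table(s1$true_labels)), rep(50L, 4), ignore_attr = TRUE)
  expect_equal(s1$tsm$series_ids[1:2], c("A1.r1", "A1.r2"))
  expect_equal(s1$tsm$series_ids[200], "D20.r10")
  s3 <- simulate_scenario(spec, seed = 43)
  expect_false(identical(s1$tsm$values, s3$tsm$values))
})

test_that("non-stationary specifications are refused", {
  expect_error(simulate_scenario(scenario_spec(1, beta = 1.1), seed = 1),
               "non-stationary")
})

test_that("the Kronecker noise induces the replicate correlation", {
  # switch off the dynamics: observed series are pure noise whose
  # within-replicate-block correlation must be the nominal 0.6
  spec <- scenario_spec(1, T = 5000, beta = 0, gamma = 0, burn_in = 10)
  sim <- simulate_scenario(spec, seed = 9)
  X <- sim$tsm$values
  R <- cor(t(X[1:20, ]))
  within <- R[1:10, 1:10][upper.tri(R[1:10, 1:10])]
  across <- R[1:10, 11:20]
  expect_equal(mean(within), 0.6, tolerance = 0.05)
  expect_lt(max(abs(across)), 0.15)
})

test_that("long-run covariances solve the discrete Lyapunov equation", {
  spec <- scenario_spec(1, T = 5000)
  sim <- simulate_scenario(spec, seed = 10)
  A <- build_coefficient_matrix(spec)
  G <- matrix(0.6, 10, 10); diag(G) <- 1
  Sigma <- diag(20) %x% G
  G0 <- oracle_lyapunov(A, Sigma, iters = 100)
  S_hat <- cov(t(sim$tsm$values))
  # implied stationary correlation of replicates of one latent series
  implied <- cov2cor(G0)[1, 2]
  observed <- cov2cor(S_hat)[1, 2]
  expect_equal(observed, implied, tolerance = 0.05)
  # and the overall covariance agrees entrywise on the correlation scale
  expect_lt(max(abs(cov2cor(S_hat) - cov2cor(G0))), 0.12)
  # lag-1 cross covariance follows the Yule-Walker relation G1 = A G0
  X <- sim$tsm$values
  G1_hat <- cov(t(X[, 2:5000]), t(X[, 1:4999]))
  expect_lt(max(abs(G1_hat - A %*% G0)) / max(abs(G0)), 0.12)
})
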
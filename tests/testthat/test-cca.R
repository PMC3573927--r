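test_that("univariate CCA reduces to the absolute Pearson correlation", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    expect_equal(cca_max(x, y, shrinkage = 0)$rho, abs(cor(x, y)),
                 tolerance = 1e-10)
  }
  x <- rnorm(30)
  expect_equal(cca_max(x, x, shrinkage = 0)$rho, 1, tolerance = 1e-8)
})

test_that("cca_max matches the generalized-eigenproblem oracle", {
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(120), 40, 3)
    Y <- matrix(rnorm(80), 40, 2)
    Y[, 1] <- Y[, 1] + 0.6 * X[, 2]
    expect_equal(cca_max(X, Y, shrinkage = 0)$rho, oracle_cca(X, Y),
                 tolerance = 1e-8)
  }
})

test_that("cca_max is invariant under invertible linear transforms", {
  set.seed(31)
  X <- matrix(rnorm(150), 50, 3)
  Y <- matrix(rnorm(100), 50, 2)
  base <- cca_max(X, Y, shrinkage = 0)$rho
  for (i in 1:4) {
    A <- matrix(rnorm(9), 3); B <- matrix(rnorm(4), 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
    while (abs(det(B)) < 0.1) B <- matrix(rnorm(4), 2)
    expect_equal(cca_max(X %*% A, Y %*% B, shrinkage = 0)$rho, base,
                 tolerance = 1e-8)
  }
})

test_that("singular blocks error without shrinkage and pass with it", {
  set.seed(41)
  X <- matrix(rnorm(60), 20, 3)
  X <- cbind(X, X[, 1] + X[, 2])     # exactly collinear
  Y <- matrix(rnorm(40), 20, 2)
  expect_error(cca_max(X, Y, shrinkage = 0), "singular")
  expect_silent(r <- cca_max(X, Y, shrinkage = 0.01))
  expect_true(r$rho >= 0 && r$rho <= 1)
})

test_that("lagged CCA detects perfect lag-1 prediction and respects nulls", {
  set.seed(51)
  T_len <- 100
  xj <- rnorm(T_len)
  xi <- c(0, xj[1:(T_len - 1)])       # x_i,t = x_j,t-1 exactly
  tsm <- ts_matrix(rbind(xi, xj))
  expect_equal(lagged_cca(tsm, from_set = 2, to_set = 1, shrinkage = 0)$rho, 1,
               tolerance = 1e-8)
  # univariate reduction: identical to lagged Pearson correlation
  a <- rnorm(T_len); b <- rnorm(T_len)
  tsm2 <- ts_matrix(rbind(a, b))
  expect_equal(lagged_cca(tsm2, from_set = 2, to_set = 1, shrinkage = 0)$rho,
               abs(cor(a[2:T_len], b[1:(T_len - 1)])), tolerance = 1e-10)
  expect_error(lagged_cca(tsm2, from_set = 1, to_set = 1), "disjoint")
  # independent white noise: small sample association on average
  rhos <- replicate(200, {
    u <- rnorm(200); v <- rnorm(200)
    lagged_cca(ts_matrix(rbind(u, v)), 1, 2, shrinkage = 0)$rho
  })
  expect_lt(mean(rhos), 0.2)
})

test_that("partial CCA with empty conditioning equals lagged CCA", {
  set.seed(61)
  tsm <- ts_matrix(matrix(rnorm(4 * 60), 4))
  a <- partial_cca(tsm, target = 1, predictor_lagged = 2,
                   conditioning = integer(0), shrinkage = 0)
  b <- lagged_cca(tsm, from_set = 2, to_set = 1, shrinkage = 0)
  expect_equal(a$rho, b$rho, tolerance = 1e-10)
})

test_that("partial CCA equals the residual-regression oracle on 3 series", {
  set.seed(71)
  for (i in 1:5) {
    X <- sim_var(matrix(c(0.5, 0.3, 0, 0, 0.4, 0.2, 0, 0, 0.3), 3,
                        byrow = TRUE), 30, seed = i)
    tsm <- ts_matrix(X)
    got <- partial_cca(tsm, target = 1, predictor_lagged = 2,
                       conditioning = 3, shrinkage = 0, reduce = "none")$rho
    y <- X[1, 2:30]; x <- X[2, 1:29]; z <- X[3, 1:29]
    expect_equal(got, abs(oracle_partial_cor(y, x, cbind(z))),
                 tolerance = 1e-8)
  }
})

test_that("conditioning removes flow that is only mediated (x -> z -> y)", {
  # chain: y depends on z's past, z on x's past; x Granger-causes y only
  # through z, so the partial association given z should collapse
  A <- matrix(0, 3, 3)
  A[1, 1] <- 0.6   # x autocorrelated, so its lag carries mediated signal
  A[2, 1] <- 0.7   # z_t <- x_{t-1}
  A[3, 2] <- 0.7   # y_t <- z_{t-1}
  marg <- part <- numeric(50)
  for (i in 1:50) {
    tsm <- ts_matrix(sim_var(A, 150, seed = 100 + i))
    marg[i] <- lagged_cca(tsm, from_set = 1, to_set = 3, shrinkage = 0)$rho
    part[i] <- partial_cca(tsm, target = 3, predictor_lagged = 1,
                           conditioning = 2, shrinkage = 0,
                           reduce = "none")$rho
  }
  expect_gt(mean(marg), 3 * mean(part))
  expect_lt(mean(part), 0.2)
})

test_that("Bartlett test returns p near 1 for a zero correlation", {
  set.seed(81)
  x <- rnorm(50)
  y <- resid(lm(rnorm(50) ~ x))       # exactly orthogonal to x
  r <- cca_max(x, y, shrinkage = 0)
  r$n_eff <- 50L
  expect_lt(r$rho, 1e-8)
  expect_gt(gc_test(r)$p_value, 0.99)
})

test_that("asymptotic test is calibrated under independence", {
  set.seed(91)
  pvals <- replicate(400, {
    u <- matrix(rnorm(60 * 2), 60)
    v <- matrix(rnorm(60 * 2), 60)
    gc_test(cca_max(u, v, shrinkage = 0))$p_value
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("permutation and asymptotic p-values agree in rank ordering", {
  set.seed(101)
  pa <- pp <- numeric(60)
  for (i in 1:60) {
    b <- runif(1, 0, 0.35)
    x <- rnorm(80)
    y <- b * x + rnorm(80)
    r <- cca_max(x, y, shrinkage = 0)
    pa[i] <- gc_test(r)$p_value
    pp[i] <- gc_test(r, method = "permutation", B = 499, seed = i)$p_value
  }
  expect_gt(cor(pa, pp, method = "spearman"), 0.9)
})

test_that("permutation p-value has the add-one form and is reproducible", {
  set.seed(111)
  x <- rnorm(60); y <- 0.3 * x + rnorm(60)
  r <- cca_max(x, y, shrinkage = 0)
  t1 <- gc_test(r, method = "permutation", B = 99, seed = 7)
  t2 <- gc_test(r, method = "permutation", B = 99, seed = 7)
  expect_equal(t1$p_value, t2$p_value)
  expect_true(t1$p_value >= 1 / 100 && t1$p_value <= 1)
  expect_equal((t1$p_value * 100) %% 1, 0)  # (1 + count) / (B + 1) grid
})

test_that("asymptotic test refuses too-small samples and suggests permutation", {
  set.seed(121)
  r <- cca_max(matrix(rnorm(24), 8, 3), matrix(rnorm(24), 8, 3),
               shrinkage = 0.05)
  expect_error(gc_test(r), "permutation")
})
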
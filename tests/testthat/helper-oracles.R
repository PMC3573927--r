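# Independent oracles used to check the package implementation on small
# instances. These deliberately take different computational routes than the
# package (generalized eigenproblem instead of whitened SVD, lm() instead of
# covariance algebra, exhaustive enumeration instead of heuristics).

# largest canonical correlation via the (unregularized) generalized
# eigenproblem on the joint covariance
oracle_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Sxx <- cov(X); Syy <- cov(Y); Sxy <- cov(X, Y)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(0, max(Re(eigen(M, only.values = TRUE)$values))))
}

# partial correlation of univariate x, y given covariate block Z, via lm()
oracle_partial_cor <- function(x, y, Z) {
  rx <- resid(lm(x ~ Z))
  ry <- resid(lm(y ~ Z))
  cor(rx, ry)
}

# best 2-partition of points by within-cluster sum of squares, exhaustively
oracle_best_bipartition <- function(U) {
  n <- nrow(U)
  best <- Inf; best_lab <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    if (length(unique(lab)) < 2L) next
    wss <- sum(sapply(split(seq_len(n), lab), function(ii) {
      Ui <- U[ii, , drop = FALSE]
      sum(scale(Ui, scale = FALSE)^2)
    }))
    if (wss < best) { best <- wss; best_lab <- lab }
  }
  list(labels = best_lab, wss = best)
}

# two-segment breakpoint by explicit lm() fits
oracle_breakpoint <- function(ks, ms) {
  n <- length(ks)
  sse <- sapply(2:(n - 2), function(q) {
    f1 <- lm(ms[1:q] ~ ks[1:q])
    f2 <- lm(ms[(q + 1):n] ~ ks[(q + 1):n])
    sum(resid(f1)^2) + sum(resid(f2)^2)
  })
  q <- (2:(n - 2))[which.min(sse)]
  list(q = q, selected_k = ks[q])
}

# stationary covariance of a VAR(1) by fixed-point iteration of the
# discrete Lyapunov equation G = A G A' + S
oracle_lyapunov <- function(A, S, iters = 200) {
  G <- S
  for (i in seq_len(iters)) G <- A %*% G %*% t(A) + S
  G
}

# small independent VAR(1) simulator (chain / custom coefficient matrix),
# standard-normal innovations, zero start, burn-in
sim_var <- function(A, T_len, seed, burn = 200, sd_noise = 1) {
  set.seed(seed)
  p <- nrow(A)
  X <- matrix(0, p, burn + T_len)
  x <- numeric(p)
  for (t in seq_len(burn + T_len)) {
    x <- drop(A %*% x) + rnorm(p, sd = sd_noise)
    X[, t] <- x
  }
  X[, (burn + 1):(burn + T_len), drop = FALSE]
}

# two independent AR(1) modules with within-module coupling, p series total
sim_two_modules <- function(p = 10, T_len = 100, seed = 1, phi = 0.5) {
  half <- p / 2
  A <- matrix(0, p, p)
  for (b in 0:1) {
    idx <- b * half + seq_len(half)
    A[idx, idx] <- 0.5 * phi / half
    for (i in idx) A[i, idx[(match(i, idx) %% half) + 1]] <- phi
  }
  A <- A * 0.9 / max(Mod(eigen(A, only.values = TRUE)$values))
  list(X = sim_var(A, T_len, seed), labels = rep(1:2, each = half), A = A)
}
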
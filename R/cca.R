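# ---- canonical correlation engine -------------------------------------------
#
# All set-level Granger quantities reduce to canonical correlations between
# covariance blocks of the aligned present/lagged windows. The engine works on
# covariance matrices so that ridge regularization and eigen-reduction of
# ill-conditioned blocks compose cleanly.

# eigendecomposition-based reduction of a covariance block to its leading
# principal axes: keep components with variance share > var_frac, but never
# fewer than min_rank (or the block dimension, if smaller).
.reduce_block <- function(S, var_frac = 0.05, min_rank = 5L) {
  m <- ncol(S)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  frac <- ev / sum(ev)
  r <- min(m, max(min_rank, sum(frac > var_frac), 1L))
  list(V = e$vectors[, seq_len(r), drop = FALSE], ev = ev[seq_len(r)], rank = r)
}

# canonical correlations from covariance blocks, with ridge on the diagonals.
# returns all roots, largest first, clamped to [0, 1].
.cca_roots_cov <- function(Sxx, Syy, Sxy, shrinkage = 0) {
  dx <- ncol(Sxx); dy <- ncol(Syy)
  isqrt <- function(S, lab) {
    e <- eigen(S, symmetric = TRUE)
    ev <- e$values + shrinkage
    if (min(ev) <= max(ev) * 1e-12)
      stop("singular ", lab, " covariance block; raise `shrinkage` or enable ",
           "PCA reduction of the block")
    e$vectors %*% (t(e$vectors) / sqrt(ev))
  }
  K <- isqrt(Sxx, "left") %*% Sxy %*% isqrt(Syy, "right")
  d <- svd(K, nu = 0, nv = 0)$d
  pmin(1, pmax(0, d[seq_len(min(dx, dy))]))
}

.new_cca_result <- function(rhos, dim_left, dim_right, n_eff, n_cond = 0L,
                            shrinkage = 0, samples = NULL) {
  out <- structure(list(rho = rhos[1L], rhos = rhos, dim_left = dim_left,
                        dim_right = dim_right, n_eff = n_eff,
                        n_cond = n_cond, shrinkage = shrinkage),
                   class = "cca_result")
  if (!is.null(samples)) attr(out, "samples") <- samples
  out
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: rho = %.4f (dims %d x %d, n_eff = %d%s)\n", x$rho,
              x$dim_left, x$dim_right, x$n_eff,
              if (x$n_cond > 0) sprintf(", %d conditioning columns", x$n_cond)
              else ""))
  invisible(x)
}

#' Largest canonical correlation between two sample blocks
#'
#' The largest canonical correlation summarizes the linear association between
#' two sets of variables. With both sides univariate it equals the absolute
#' Pearson correlation. Covariances can be ridge-regularized through
#' `shrinkage` when a block is ill-conditioned.
#'
#' @param left,right Numeric matrices (or vectors) with observations in rows;
#'   both must have the same number of rows.
#' @param shrinkage Non-negative ridge added to the diagonal of each block
#'   covariance. `0` computes plain CCA and fails with an informative error on
#'   singular blocks.
#' @return A `cca_result` with elements `rho` (largest root), `rhos` (all
#'   roots), `dim_left`, `dim_right`, `n_eff`.
#' @examples
#' x <- matrix(rnorm(120), ncol = 3)
#' y <- matrix(rnorm(80), ncol = 2)
#' cca_max(x, y, shrinkage = 0)$rho
#' @export
cca_max <- function(left, right, shrinkage = 0.01) {
  left <- as.matrix(left); right <- as.matrix(right)
  if (nrow(left) != nrow(right))
    stop("left and right must have the same number of rows (time points)")
  if (shrinkage < 0) stop("shrinkage must be >= 0")
  n <- nrow(left)
  Sxx <- stats::cov(left); Syy <- stats::cov(right)
  Sxy <- stats::cov(left, right)
  rhos <- .cca_roots_cov(Sxx, Syy, Sxy, shrinkage)
  .new_cca_result(rhos, ncol(left), ncol(right), n_eff = n,
                  shrinkage = shrinkage,
                  samples = list(left = left, right = right))
}

.check_series_set <- function(tsm, idx, what = "series set") {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop(what, " must be non-empty")
  if (anyDuplicated(idx)) stop(what, " has duplicated indices")
  if (any(idx < 1L | idx > tsm$p)) stop(what, " indices out of range")
  idx
}

#' Lagged canonical correlation between two disjoint sets of series
#'
#' Quantifies the Granger-causal information flow `from_set -> to_set`: the
#' largest canonical correlation between the target set at times
#' `lag+1 .. T` and the source set at times `1 .. T-lag`.
#'
#' @param tsm A [ts_matrix].
#' @param from_set,to_set Disjoint integer index vectors of series (rows).
#' @param lag Positive lag; defaults to the matrix's `lag_order`.
#' @param shrinkage Ridge passed to [cca_max()].
#' @return A `cca_result` with `n_eff = T - lag`.
#' @export
lagged_cca <- function(tsm, from_set, to_set, lag = tsm$lag_order,
                       shrinkage = 0.01) {
  stopifnot(inherits(tsm, "ts_matrix"))
  from_set <- .check_series_set(tsm, from_set, "from_set")
  to_set <- .check_series_set(tsm, to_set, "to_set")
  if (length(intersect(from_set, to_set)) > 0L)
    stop("from_set and to_set must be disjoint")
  T_len <- tsm$T
  if (T_len - lag < 3L) stop("T - lag must be at least 3")
  tgt <- t(tsm$values[to_set, (lag + 1L):T_len, drop = FALSE])
  src <- t(tsm$values[from_set, 1L:(T_len - lag), drop = FALSE])
  cca_max(tgt, src, shrinkage = shrinkage)
}

# ridge residualization of Y on covariate block Z (columns), intercept-free
# after centering; shrinkage = 0 requires Z well-conditioned.
.residualize <- function(Y, Z, shrinkage = 0) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  if (is.null(Z) || ncol(Z) == 0L) return(Y)
  Z <- scale(as.matrix(Z), center = TRUE, scale = FALSE)
  G <- crossprod(Z)
  if (shrinkage == 0) {
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * 1e-12 || ncol(Z) >= nrow(Z))
      stop("conditioning block is (near) rank deficient with shrinkage = 0; ",
           "raise `shrinkage` or reduce the block")
  } else {
    diag(G) <- diag(G) + shrinkage * nrow(Z)
  }
  Y - Z %*% solve(G, crossprod(Z, Y))
}

#' Partial lagged canonical correlation (conditional Granger causality)
#'
#' Measures the information flow from `predictor_lagged` (at `t - lag`) to
#' `target` (at `t`) after the lag-`lag` values of a conditioning set have
#' been regressed out of both sides. A zero partial canonical correlation
#' encodes Granger non-causality in the linear VAR setting.
#'
#' @param tsm A [ts_matrix].
#' @param target,predictor_lagged Disjoint series index sets.
#' @param conditioning Series indices whose lagged values are partialized
#'   out. Defaults to all series outside `target` and `predictor_lagged`;
#'   pass `integer(0)` for an unconditional [lagged_cca()].
#' @param lag Positive lag.
#' @param shrinkage Ridge used both in the residualizing regression and the
#'   final CCA.
#' @param reduce How to handle ill-conditioned multivariate blocks before
#'   residualization: `"auto"` eigen-reduces any block whose dimension is at
#'   least `n_eff / 2` (components with variance share > 5%, floor 5),
#'   `"none"` never reduces, `"always"` reduces every multivariate block.
#' @return A `cca_result`; `n_cond` records the number of conditioning
#'   columns for downstream degree-of-freedom corrections.
#' @export
partial_cca <- function(tsm, target, predictor_lagged, conditioning = NULL,
                        lag = tsm$lag_order, shrinkage = 0.01,
                        reduce = c("auto", "none", "always")) {
  stopifnot(inherits(tsm, "ts_matrix"))
  reduce <- match.arg(reduce)
  target <- .check_series_set(tsm, target, "target")
  predictor_lagged <- .check_series_set(tsm, predictor_lagged, "predictor_lagged")
  if (length(intersect(target, predictor_lagged)) > 0L)
    stop("target and predictor_lagged must be disjoint")
  if (is.null(conditioning))
    conditioning <- setdiff(seq_len(tsm$p), union(target, predictor_lagged))
  conditioning <- as.integer(conditioning)
  T_len <- tsm$T
  n_eff <- T_len - lag
  tgt <- t(tsm$values[target, (lag + 1L):T_len, drop = FALSE])
  prd <- t(tsm$values[predictor_lagged, 1L:(T_len - lag), drop = FALSE])
  Z <- if (length(conditioning) > 0L)
    t(tsm$values[conditioning, 1L:(T_len - lag), drop = FALSE]) else NULL
  shrink_blocks <- function(M) {
    if (is.null(M) || ncol(M) < 2L) return(M)
    big <- ncol(M) >= n_eff / 2
    if (reduce == "always" || (reduce == "auto" && big)) {
      red <- .reduce_block(stats::cov(M))
      M %*% red$V
    } else M
  }
  tgt <- shrink_blocks(tgt); prd <- shrink_blocks(prd); Z <- shrink_blocks(Z)
  rtg <- .residualize(tgt, Z, shrinkage)
  rpd <- .residualize(prd, Z, shrinkage)
  res <- cca_max(rtg, rpd, shrinkage = shrinkage)
  res$n_eff <- n_eff
  res$n_cond <- if (is.null(Z)) 0L else ncol(Z)
  res
}

#' Test the null of Granger non-causality (zero canonical correlation)
#'
#' Tests `H0: rho = 0` for a fitted (partial) canonical correlation. The
#' asymptotic method is the Bartlett-Lawley chi-square statistic on all
#' canonical roots jointly,
#' `-(n' - 1 - (p + q + 1)/2) * sum(log(1 - rho_k^2))` with `p * q` degrees
#' of freedom, where `n'` is the effective sample size minus the number of
#' conditioning columns. The permutation method re-estimates the largest root
#' after circularly shifting the predictor block in time, which preserves
#' each block's autocorrelation while breaking the cross dependence.
#'
#' @param result A `cca_result` from [cca_max()], [lagged_cca()] or
#'   [partial_cca()].
#' @param method `"asymptotic"` or `"permutation"`.
#' @param B Number of circular shifts for the permutation method.
#' @param seed Optional seed for the permutation draws.
#' @return A `gc_test_result` with `rho_hat`, `statistic`, `p_value`, `method`.
#' @export
gc_test <- function(result, method = c("asymptotic", "permutation"),
                    B = 999L, seed = NULL) {
  stopifnot(inherits(result, "cca_result"))
  method <- match.arg(method)
  dl <- result$dim_left; dr <- result$dim_right
  nprime <- result$n_eff - result$n_cond
  if (method == "asymptotic") {
    if (nprime <= dl + dr + 2L)
      stop("effective sample too small for the asymptotic test ",
           "(need n_eff - n_cond > dim_left + dim_right + 2); ",
           "use method = \"permutation\"")
    stat <- -(nprime - 1 - (dl + dr + 1) / 2) *
      sum(log(pmax(1e-12, 1 - result$rhos^2)))
    pval <- stats::pchisq(stat, df = dl * dr, lower.tail = FALSE)
  } else {
    smp <- attr(result, "samples")
    if (is.null(smp))
      stop("permutation test requires a result carrying its sample blocks")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    n <- nrow(smp$right)
    shifts <- sample.int(n - 1L, B, replace = TRUE)
    rho_perm <- vapply(shifts, function(s) {
      idx <- c((s + 1L):n, 1L:s)
      .cca_roots_cov(stats::cov(smp$left), stats::cov(smp$right),
                     stats::cov(smp$left, smp$right[idx, , drop = FALSE]),
                     result$shrinkage)[1L]
    }, numeric(1))
    stat <- result$rho
    pval <- (1 + sum(rho_perm >= result$rho)) / (B + 1)
  }
  structure(list(rho_hat = result$rho, statistic = stat, p_value = pval,
                 method = method, df = dl * dr),
            class = "gc_test_result")
}

#' @export
print.gc_test_result <- function(x, ...) {
  cat(sprintf("Granger non-causality test (%s): rho_hat = %.4f, p = %.4g\n",
              x$method, x$rho_hat, x$p_value))
  invisible(x)
}
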
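# ---- Granger-causality distance and degrees ---------------------------------

# directional set-level CCA magnitude computed from the lag-window covariance
# cache: target block at present indices `pres`, source block at lagged
# indices `lagg` (both refer to series rows; `lagg` is offset by p inside).
# Multivariate sides are eigen-reduced (variance share > var_frac, floor
# min_rank) and ridge-regularized.
.set_cca_rho <- function(lc, pres, lagg, shrinkage = 0.01, var_frac = 0.05,
                         min_rank = 5L) {
  C <- lc$C; p <- lc$p
  ip <- pres; il <- lagg + p
  Sxx <- C[ip, ip, drop = FALSE]
  Syy <- C[il, il, drop = FALSE]
  Sxy <- C[ip, il, drop = FALSE]
  if (length(ip) > 1L) {
    rx <- .reduce_block(Sxx, var_frac, min_rank)
    Sxx <- diag(rx$ev, nrow = rx$rank)
    Sxy <- crossprod(rx$V, Sxy)
  }
  if (length(il) > 1L) {
    ry <- .reduce_block(Syy, var_frac, min_rank)
    Syy <- diag(ry$ev, nrow = ry$rank)
    Sxy <- Sxy %*% ry$V
  }
  .cca_roots_cov(Sxx, Syy, Sxy, shrinkage)[1L]
}

#' Granger-causality distance between two disjoint sets of series
#'
#' `dist(i, j) = 1 - (|CCA(X_t^i, X_{t-1}^j)| + |CCA(X_t^j, X_{t-1}^i)|) / 2`:
#' one minus the average of the two directional lagged canonical correlation
#' magnitudes. The average makes the distance symmetric; the stronger the
#' information flow in either direction, the smaller the distance. Values lie
#' in `[0, 1]`; the triangle inequality is not guaranteed.
#'
#' Multivariate sides are represented by their leading principal axes
#' (variance share > `var_frac`, at least `min_rank` components) before the
#' CCA, which keeps the covariance blocks well conditioned.
#'
#' @param tsm A [ts_matrix] (standardized internally).
#' @param set_i,set_j Disjoint, non-empty series index sets.
#' @param lag Positive lag.
#' @param shrinkage Ridge regularization of the reduced blocks.
#' @param var_frac,min_rank Reduction rule for multivariate sides.
#' @return A number in `[0, 1]`.
#' @export
gc_distance <- function(tsm, set_i, set_j, lag = tsm$lag_order,
                        shrinkage = 0.01, var_frac = 0.05, min_rank = 5L) {
  stopifnot(inherits(tsm, "ts_matrix"))
  set_i <- .check_series_set(tsm, set_i, "set_i")
  set_j <- .check_series_set(tsm, set_j, "set_j")
  if (length(intersect(set_i, set_j)) > 0L)
    stop("set_i and set_j must be disjoint")
  lc <- .lag_cov(standardize(tsm), lag)
  r_ij <- .set_cca_rho(lc, set_i, set_j, shrinkage, var_frac, min_rank)
  r_ji <- .set_cca_rho(lc, set_j, set_i, shrinkage, var_frac, min_rank)
  1 - (r_ij + r_ji) / 2
}

# degree of a present/lagged block pair given a covariance cache
.degree_rho <- function(lc, pres, lagg, shrinkage, var_frac, min_rank) {
  .set_cca_rho(lc, pres, lagg, shrinkage, var_frac, min_rank)
}

#' Granger-causality degree of a single series
#'
#' The in-degree of series `i` is the canonical correlation magnitude between
#' `x_{i,t}` and the lagged values of the rest of the network; the out-degree
#' is the magnitude between the rest of the network at `t` and `x_{i,t-lag}`.
#' The degree is their average and measures the total information flow
#' passing through the series.
#'
#' @param tsm A [ts_matrix].
#' @param i Series index.
#' @param mode `"total"` (default), `"in"` or `"out"`.
#' @inheritParams gc_distance
#' @return A number in `[0, 1]`.
#' @export
series_degree <- function(tsm, i, mode = c("total", "in", "out"),
                          lag = tsm$lag_order, shrinkage = 0.01,
                          var_frac = 0.05, min_rank = 5L) {
  set_degree(tsm, i, mode = mode, lag = lag, shrinkage = shrinkage,
             var_frac = var_frac, min_rank = min_rank)
}

#' Granger-causality degree of a set of series (sub-network)
#'
#' Extends [series_degree()] to a candidate sub-network: the in-degree is the
#' set-level CCA magnitude between the set at `t` and the lagged complement
#' of the set, the out-degree the reverse, and the degree their average. The
#' complement excludes the set itself, so a well-separated sub-network has a
#' small degree (little cross-boundary flow) even when the flow inside it is
#' strong.
#'
#' @param tsm A [ts_matrix].
#' @param s Non-empty set of series indices, a strict subset of all series.
#' @inheritParams series_degree
#' @return A number in `[0, 1]`.
#' @export
set_degree <- function(tsm, s, mode = c("total", "in", "out"),
                       lag = tsm$lag_order, shrinkage = 0.01,
                       var_frac = 0.05, min_rank = 5L) {
  stopifnot(inherits(tsm, "ts_matrix"))
  mode <- match.arg(mode)
  s <- .check_series_set(tsm, s, "series set")
  rest <- setdiff(seq_len(tsm$p), s)
  if (length(rest) == 0L)
    stop("degree is undefined for the full network (empty complement)")
  lc <- .lag_cov(standardize(tsm), lag)
  d_in <- function() .degree_rho(lc, s, rest, shrinkage, var_frac, min_rank)
  d_out <- function() .degree_rho(lc, rest, s, shrinkage, var_frac, min_rank)
  switch(mode,
         "in" = d_in(),
         "out" = d_out(),
         "total" = (d_in() + d_out()) / 2)
}
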
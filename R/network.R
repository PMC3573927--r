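# ---- cluster-level Granger-causality network --------------------------------

#' Eigen-time series of each cluster
#'
#' Summarizes every cluster by its principal-component time series
#' ("eigen-time series"): PCA is run across the cluster's series (time points
#' are the observations) and the components accounting for more than
#' `var_frac` of the temporal variance are retained (always at least one).
#' This removes the redundancy of co-expressed series before set-level
#' testing.
#'
#' @param tsm A [ts_matrix] (standardized internally).
#' @param assign A `cluster_assignment` or integer label vector.
#' @param var_frac Variance-share retention threshold (default 5%).
#' @return An `eigen_series_set`: list with `scores` (per cluster, a
#'   `T x r` matrix of component series), `variance_fractions`, `labels`.
#' @export
extract_eigen_series <- function(tsm, assign, var_frac = 0.05) {
  stopifnot(inherits(tsm, "ts_matrix"))
  labels <- if (inherits(assign, "cluster_assignment")) assign$labels
            else as.integer(assign)
  if (length(labels) != tsm$p) stop("labels length must equal number of series")
  tsm <- standardize(tsm)
  ks <- sort(unique(labels))
  scores <- vector("list", length(ks))
  fracs <- vector("list", length(ks))
  for (m in seq_along(ks)) {
    idx <- which(labels == ks[m])
    Xi <- t(tsm$values[idx, , drop = FALSE])          # T x m
    if (length(idx) == 1L) {
      scores[[m]] <- Xi
      fracs[[m]] <- 1
      next
    }
    e <- eigen(stats::cov(Xi), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    frac <- ev / sum(ev)
    r <- max(1L, sum(frac > var_frac))
    scores[[m]] <- Xi %*% e$vectors[, seq_len(r), drop = FALSE]
    fracs[[m]] <- frac[seq_len(r)]
  }
  names(scores) <- names(fracs) <- as.character(ks)
  structure(list(scores = scores, variance_fractions = fracs,
                 labels = labels, T = tsm$T),
            class = "eigen_series_set")
}

#' Infer the cluster-to-cluster Granger-causality network
#'
#' For every ordered pair of clusters `(j, i)` the partial canonical
#' correlation between cluster `i`'s eigen-time series at `t` and cluster
#' `j`'s at `t - lag` is computed, conditioning on the lagged eigen-time
#' series of all remaining clusters (for `i != j` this includes the target's
#' own past, so a significant edge means `j`'s past adds information beyond
#' everything else; the diagonal tests a cluster's dependence on its own past
#' given the other clusters). Each edge carries the test p-value and
#' significance flags at the two conventional thresholds.
#'
#' @param eigs An `eigen_series_set` with at least two clusters.
#' @param lag Positive lag (default 1).
#' @param method Test passed to [gc_test()].
#' @param alpha Two significance levels, solid and dashed (defaults 0.05 and
#'   0.10).
#' @param p_adjust Optional multiple-testing correction (a method name for
#'   [stats::p.adjust()]); default `"none"`, matching raw per-edge testing.
#' @param B,seed Permutation settings when `method = "permutation"`.
#' @return A `cluster_network`: list with `edges` (data.frame: `from`, `to`,
#'   `rho_hat`, `p_value`, `significant_0.05`, `significant_0.10`) and
#'   `alpha`.
#' @export
infer_network <- function(eigs, lag = 1L,
                          method = c("asymptotic", "permutation"),
                          alpha = c(0.05, 0.10), p_adjust = "none",
                          B = 999L, seed = NULL) {
  stopifnot(inherits(eigs, "eigen_series_set"))
  method <- match.arg(method)
  cl <- names(eigs$scores)
  if (length(cl) < 2L) stop("need at least two clusters")
  T_len <- eigs$T
  n_eff <- T_len - lag
  pres <- lapply(eigs$scores, function(S) S[(lag + 1L):T_len, , drop = FALSE])
  lagd <- lapply(eigs$scores, function(S) S[1L:(T_len - lag), , drop = FALSE])
  rows <- list(); ri <- 0L
  for (j in seq_along(cl)) for (i in seq_along(cl)) {
    # conditioning: lagged eigen-series of every cluster except the predictor
    # (for i != j this keeps the target's own past in the conditioning set)
    cond <- setdiff(seq_along(cl), j)
    Z <- if (length(cond)) do.call(cbind, lagd[cond]) else NULL
    rtg <- .residualize(pres[[i]], Z, shrinkage = 0)
    rpd <- .residualize(lagd[[j]], Z, shrinkage = 0)
    res <- cca_max(rtg, rpd, shrinkage = 0)
    res$n_eff <- n_eff
    res$n_cond <- if (is.null(Z)) 0L else ncol(Z)
    tst <- gc_test(res, method = method, B = B,
                   seed = if (is.null(seed)) NULL else seed + ri)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(from = cl[j], to = cl[i], rho_hat = res$rho,
                             p_value = tst$p_value)
  }
  edges <- do.call(rbind, rows)
  edges$p_value <- stats::p.adjust(edges$p_value, method = p_adjust)
  edges$significant_0.05 <- edges$p_value < alpha[1]
  edges$significant_0.10 <- edges$p_value < alpha[2]
  structure(list(edges = edges, alpha = alpha), class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf("cluster_network: %d ordered pairs, %d significant at %.2f\n",
              nrow(x$edges), sum(x$edges$significant_0.05), x$alpha[1]))
  print(x$edges, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write the edge list as TSV
#'
#' @param net A `cluster_network`.
#' @param path Output file.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "cluster_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
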
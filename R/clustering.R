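# ---- similarity graph and spectral clustering -------------------------------

# pairwise directional lag correlations: M[i, j] = cor(x_i present, x_j lagged)
.lag_cor_matrix <- function(X, lag) {
  T_len <- ncol(X)
  stats::cor(t(X[, (lag + 1L):T_len, drop = FALSE]),
             t(X[, 1L:(T_len - lag), drop = FALSE]))
}

# per-series in/out degrees against the lagged/present complement, with ridge
# regularization only. One matrix inverse per direction; each series is then
# a rank-one downdate (exact for the ridge-regularized problem).
.cca_degrees <- function(lc, shrinkage = 0.01) {
  C <- lc$C; p <- lc$p
  ip <- seq_len(p); il <- ip + p
  Minv_l <- solve(C[il, il] + shrinkage * diag(p))
  Minv_p <- solve(C[ip, ip] + shrinkage * diag(p))
  Cpl <- C[ip, il]
  indeg <- outdeg <- numeric(p)
  for (i in ip) {
    c1 <- Cpl[i, ]; c1[i] <- 0
    v <- Minv_l %*% c1
    q1 <- sum(c1 * v) - v[i]^2 / Minv_l[i, i]
    indeg[i] <- sqrt(max(0, min(1, q1 / C[i, i])))
    c2 <- Cpl[, i]; c2[i] <- 0
    v2 <- Minv_p %*% c2
    q2 <- sum(c2 * v2) - v2[i]^2 / Minv_p[i, i]
    outdeg[i] <- sqrt(max(0, min(1, q2 / C[i + p, i + p])))
  }
  (indeg + outdeg) / 2
}

#' Granger-causality similarity graph and Laplacian
#'
#' Builds the weighted adjacency `W[i, j] = 1 - dist(i, j)` from the pairwise
#' Granger-causality distance (so `W` is symmetric with entries in `[0, 1]`
#' and a zero diagonal), a degree vector `d`, and the Laplacian `L = D - W`.
#'
#' With `degree_mode = "cca_degree"` the diagonal `D` holds each series'
#' Granger-causality degree: the average of the ridge-regularized canonical
#' correlations between the series and the lagged (respectively leading)
#' complement of the network. With `"row_sum"` it holds the classical
#' Laplacian row sums of `W`, a fallback useful when the full-network degree
#' is badly conditioned.
#'
#' @param tsm A [ts_matrix] (standardized internally).
#' @param degree_mode `"cca_degree"` (default) or `"row_sum"`.
#' @param lag Positive lag for the pairwise and degree CCAs.
#' @param shrinkage Ridge used in the degree computation.
#' @return A `gc_adjacency`: list with `W`, `d`, `L`, `degree_mode`,
#'   `series_ids`.
#' @export
build_adjacency <- function(tsm, degree_mode = c("cca_degree", "row_sum"),
                            lag = tsm$lag_order, shrinkage = 0.01) {
  stopifnot(inherits(tsm, "ts_matrix"))
  degree_mode <- match.arg(degree_mode)
  if (tsm$p < 2L) stop("need at least two series")
  tsm <- standardize(tsm)
  M <- abs(.lag_cor_matrix(tsm$values, lag))
  W <- (M + t(M)) / 2
  diag(W) <- 0
  d <- if (degree_mode == "cca_degree") {
    .cca_degrees(.lag_cov(tsm, lag), shrinkage)
  } else {
    rowSums(W)
  }
  L <- diag(d) - W
  structure(list(W = W, d = d, L = L, degree_mode = degree_mode,
                 series_ids = tsm$series_ids),
            class = "gc_adjacency")
}

#' Spectral embedding of the Granger-causality graph
#'
#' Computes `k` eigenvectors of the Laplacian `L = D - W` and stacks them as
#' columns of `U`; the rows of `U` are the points that get clustered. The
#' default takes the eigenvectors of the `k` smallest eigenvalues, as in
#' classical unnormalized spectral clustering, where the leading null-space
#' directions of a block Laplacian are the cluster indicators.
#' `eig_order = "largest"` is available as a switch.
#'
#' Column signs are fixed (first entry of largest magnitude made positive)
#' so the embedding is deterministic.
#'
#' @param adj A `gc_adjacency` from [build_adjacency()].
#' @param k Number of eigenvectors, `2 <= k <= p`.
#' @param eig_order `"smallest"` (default) or `"largest"`.
#' @return A `spectral_embedding`: list with `U` (`p x k`, orthonormal
#'   columns) and `eigenvalues` (ascending for `"smallest"`, descending for
#'   `"largest"`).
#' @export
spectral_embed <- function(adj, k, eig_order = c("smallest", "largest")) {
  stopifnot(inherits(adj, "gc_adjacency"))
  eig_order <- match.arg(eig_order)
  p <- nrow(adj$L)
  if (k < 1L || k > p) stop("k must be between 1 and p")
  e <- eigen(adj$L, symmetric = TRUE)  # eigenvalues in decreasing order
  sel <- if (eig_order == "smallest") rev(seq.int(p - k + 1L, p)) else seq_len(k)
  U <- e$vectors[, sel, drop = FALSE]
  for (j in seq_len(ncol(U))) {
    m <- which.max(abs(U[, j]))
    if (U[m, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, eigenvalues = e$values[sel], eig_order = eig_order),
            class = "spectral_embedding")
}

# single Lloyd run from sampled distinct rows; returns NULL on empty cluster
.kmeans_once <- function(U, k, iter_max) {
  start <- sample.int(nrow(U), k)
  centers <- U[start, , drop = FALSE]
  if (anyDuplicated(round(centers, 12))) return(NULL)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(U, centers = centers, iter.max = iter_max,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km) || any(km$size == 0L)) return(NULL)
  km
}

#' k-means on the spectral embedding
#'
#' Runs Lloyd's k-means on the rows of the embedding matrix `U`, keeping the
#' best of `n_init` random initializations (initial centers are sampled data
#' rows; an initialization that collapses a cluster is redrawn and counted).
#' Seeded and reproducible.
#'
#' @param emb A `spectral_embedding`.
#' @param k Number of clusters.
#' @param n_init Number of random initializations (the default follows the
#'   common practice of using many restarts to approach the global optimum).
#' @param seed Optional integer seed.
#' @param iter_max Maximum Lloyd iterations per initialization.
#' @return A `cluster_assignment`: list with `labels` (integers `1..k`),
#'   `k`, and `inertia` (within-cluster sum of squares at the optimum).
#' @export
kmeans_embed <- function(emb, k, n_init = 100L, seed = NULL, iter_max = 300L) {
  stopifnot(inherits(emb, "spectral_embedding"))
  U <- emb$U
  if (k > nrow(U)) stop("k cannot exceed the number of series")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  best <- NULL
  tries <- 0L; done <- 0L
  while (done < n_init && tries < 20L * n_init) {
    tries <- tries + 1L
    km <- .kmeans_once(U, k, iter_max)
    if (is.null(km)) next
    done <- done + 1L
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for every initialization")
  structure(list(labels = as.integer(best$cluster), k = as.integer(k),
                 inertia = best$tot.withinss),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: k = %d, sizes = %s\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Functional clustering of time series by Granger causality
#'
#' The full clustering algorithm: build the Granger-causality similarity
#' graph, embed it spectrally, and cluster the embedded points with k-means.
#' Series end up in the same cluster when the Granger-causal information
#' flow among them is strong and the flow to the rest of the network weak.
#'
#' @param tsm A [ts_matrix].
#' @param k Number of sub-networks.
#' @param degree_mode,eig_order,shrinkage,lag See [build_adjacency()] and
#'   [spectral_embed()].
#' @param n_init,seed See [kmeans_embed()].
#' @return A `cluster_assignment`.
#' @examples
#' spec <- scenario_spec(1, T = 60)
#' sim <- simulate_scenario(spec, seed = 1)
#' cl <- functional_cluster(sim$tsm, k = 4, seed = 1)
#' table(cl$labels, sim$true_labels)
#' @export
functional_cluster <- function(tsm, k, degree_mode = "cca_degree",
                               eig_order = "smallest", lag = tsm$lag_order,
                               shrinkage = 0.01, n_init = 100L, seed = NULL) {
  adj <- build_adjacency(tsm, degree_mode = degree_mode, lag = lag,
                         shrinkage = shrinkage)
  emb <- spectral_embed(adj, k, eig_order = eig_order)
  kmeans_embed(emb, k, n_init = n_init, seed = seed)
}

#' Write cluster labels as a two-column TSV
#'
#' @param assign A `cluster_assignment`.
#' @param series_ids Character vector of series identifiers.
#' @param path Output file.
#' @export
write_cluster_assignment <- function(assign, series_ids, path) {
  stopifnot(inherits(assign, "cluster_assignment"),
            length(series_ids) == length(assign$labels))
  utils::write.table(
    data.frame(series_id = series_ids, cluster_label = assign$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
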
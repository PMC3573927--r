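# ---- cluster index (silhouette variant) and choice of k ---------------------

# silhouette of every series given labels, from a lag-covariance cache.
# Each cluster is represented once by the leading principal axes of its
# present and lagged covariance blocks (variance share > var_frac, floor
# min_rank); a(i) and b(i) are then cheap projections. See the methods
# vignette for why the series is not removed from its own cluster's
# representation.
.silhouette_from_cov <- function(lc, labels, shrinkage = 0.01,
                                 var_frac = 0.05, min_rank = 5L) {
  C <- lc$C; p <- lc$p
  k <- max(labels)
  reps <- lapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(list(idx = idx, uni = TRUE))
    list(idx = idx, uni = FALSE,
         lag = .reduce_block(C[idx + p, idx + p, drop = FALSE], var_frac, min_rank),
         pres = .reduce_block(C[idx, idx, drop = FALSE], var_frac, min_rank))
  })
  a <- b <- s <- numeric(p)
  for (i in seq_len(p)) {
    d <- rep(NA_real_, k)
    for (cl in seq_len(k)) {
      rp <- reps[[cl]]; idx <- rp$idx
      if (rp$uni) {
        if (identical(idx, i)) next
        r1 <- abs(C[i, idx + p]) / sqrt(C[i, i] * C[idx + p, idx + p])
        r2 <- abs(C[i + p, idx]) / sqrt(C[i + p, i + p] * C[idx, idx])
      } else {
        cv1 <- crossprod(rp$lag$V, C[idx + p, i])
        r1 <- sqrt(max(0, min(1, sum(cv1^2 / (rp$lag$ev + shrinkage)) / C[i, i])))
        cv2 <- crossprod(rp$pres$V, C[idx, i + p])
        r2 <- sqrt(max(0, min(1, sum(cv2^2 / (rp$pres$ev + shrinkage)) / C[i + p, i + p])))
      }
      d[cl] <- 1 - (r1 + r2) / 2
    }
    own <- labels[i]
    if (sum(labels == own) < 2L) { a[i] <- NA; b[i] <- NA; s[i] <- 0; next }
    a[i] <- d[own]
    b[i] <- min(d[-own], na.rm = TRUE)
    s[i] <- if (max(a[i], b[i]) > 0) (b[i] - a[i]) / max(a[i], b[i]) else 0
  }
  structure(list(s = s, a = a, b = b, mean_s = mean(s)),
            class = "silhouette_profile")
}

#' Dissimilarity between one series and a cluster
#'
#' The set-level Granger-causality distance between series `i` and a cluster
#' of series, used as the building block of the cluster index: the cluster is
#' represented by its leading principal axes and the two directional lagged
#' canonical correlations are averaged as in [gc_distance()]. If `i` belongs
#' to the cluster it is removed first.
#'
#' @param tsm A [ts_matrix].
#' @param i Series index.
#' @param cluster Series indices of the cluster.
#' @inheritParams gc_distance
#' @return A number in `[0, 1]`.
#' @export
series_cluster_dissimilarity <- function(tsm, i, cluster,
                                         lag = tsm$lag_order,
                                         shrinkage = 0.01, var_frac = 0.05,
                                         min_rank = 5L) {
  cluster <- setdiff(as.integer(cluster), as.integer(i))
  if (length(cluster) == 0L)
    stop("cluster must contain at least one series other than i")
  gc_distance(tsm, i, cluster, lag = lag, shrinkage = shrinkage,
              var_frac = var_frac, min_rank = min_rank)
}

#' Cluster index (silhouette variant) of a clustering
#'
#' For every series, `a(i)` is its Granger-causality distance to its own
#' sub-network and `b(i)` the smallest distance to any other sub-network;
#' the cluster index is `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, in
#' `[-1, 1]`. Values near 1 mean the series sits deep inside its sub-network
#' in terms of information flow; values near 0 put it on a border; negative
#' values suggest the neighboring sub-network fits better. A series alone in
#' its cluster gets `s(i) = 0`.
#'
#' @param tsm A [ts_matrix].
#' @param assign A `cluster_assignment` (or an integer label vector) with at
#'   least two clusters.
#' @inheritParams gc_distance
#' @return A `silhouette_profile`: list with `s`, `a`, `b`, `mean_s`.
#' @export
gc_silhouette <- function(tsm, assign, lag = tsm$lag_order, shrinkage = 0.01,
                          var_frac = 0.05, min_rank = 5L) {
  stopifnot(inherits(tsm, "ts_matrix"))
  labels <- if (inherits(assign, "cluster_assignment")) assign$labels
            else as.integer(assign)
  if (length(labels) != tsm$p) stop("labels length must equal number of series")
  if (length(unique(labels)) < 2L)
    stop("the cluster index needs at least two clusters")
  labels <- match(labels, sort(unique(labels)))  # contiguous 1..k
  lc <- .lag_cov(standardize(tsm), lag)
  .silhouette_from_cov(lc, labels, shrinkage, var_frac, min_rank)
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat(sprintf("silhouette_profile: mean s = %.3f over %d series\n",
              x$mean_s, length(x$s)))
  invisible(x)
}

#' Two-segment breakpoint on the cluster-index curve
#'
#' Fits two ordinary least-squares lines to the mean-cluster-index-versus-k
#' curve, one through the first `q` points and one through the rest, for
#' every split leaving at least two points per segment, and returns the `q`
#' minimizing the total sum of squared errors (smallest `q` on ties). The
#' selected number of clusters is the last point of the first segment: the
#' index stays level while clusters are genuine and drops abruptly once a
#' true sub-network is split.
#'
#' @param ks Strictly increasing integer vector of scanned cluster counts
#'   (at least 4 values).
#' @param mean_s_per_k Matching vector of mean cluster indices.
#' @return A list with `q` (breakpoint index), `selected_k`, and `sse`.
#' @examples
#' detect_breakpoint(2:6, c(0.60, 0.60, 0.60, 0.30, 0.25))
#' @export
detect_breakpoint <- function(ks, mean_s_per_k) {
  ks <- as.numeric(ks); y <- as.numeric(mean_s_per_k)
  n <- length(ks)
  if (n < 4L) stop("need at least 4 scanned k values")
  if (length(y) != n) stop("ks and mean_s_per_k lengths differ")
  if (any(diff(ks) <= 0)) stop("ks must be strictly increasing")
  sse_fit <- function(ii) {
    f <- stats::lsfit(ks[ii], y[ii])
    sum(f$residuals^2)
  }
  best <- Inf; bq <- NA_integer_
  for (q in 2L:(n - 2L)) {
    sse <- sse_fit(1:q) + sse_fit((q + 1L):n)
    if (sse < best - 1e-12) { best <- sse; bq <- q }
  }
  list(q = bq, selected_k = as.integer(ks[bq]), sse = best)
}

#' Choose the number of sub-networks by silhouette and breakpoint
#'
#' Runs the functional clustering for every `k` in `k_min..k_max`, computes
#' the mean cluster index of each partition, and selects the number of
#' sub-networks with the two-regression breakpoint rule. The similarity
#' graph, its Laplacian spectrum and the covariance cache are computed once
#' and shared across `k`.
#'
#' @param tsm A [ts_matrix].
#' @param k_min,k_max Scan range; defaults 2 and `min(10, p - 1)`.
#' @param degree_mode,eig_order,shrinkage,lag See [functional_cluster()].
#' @param n_init,seed k-means initializations per `k` and base seed (each `k`
#'   uses `seed + k` so runs are reproducible).
#' @param var_frac,min_rank Reduction rule for the cluster representations.
#' @return A `k_scan`: list with `ks`, `mean_s_per_k`, `assignments` (one
#'   `cluster_assignment` per k), `selected_k`, `breakpoint_q`.
#' @export
select_num_clusters <- function(tsm, k_min = 2L,
                                k_max = min(10L, tsm$p - 1L),
                                degree_mode = "cca_degree",
                                eig_order = "smallest",
                                lag = tsm$lag_order, shrinkage = 0.01,
                                n_init = 100L, seed = NULL,
                                var_frac = 0.05, min_rank = 5L) {
  stopifnot(inherits(tsm, "ts_matrix"))
  if (k_max > tsm$p - 1L) stop("k_max must be at most p - 1")
  if (k_max - k_min < 3L) stop("scan at least 4 values of k")
  tsm_s <- standardize(tsm)
  adj <- build_adjacency(tsm_s, degree_mode = degree_mode, lag = lag,
                         shrinkage = shrinkage)
  e <- eigen(adj$L, symmetric = TRUE)
  lc <- .lag_cov(tsm_s, lag)
  ks <- seq.int(k_min, k_max)
  mean_s <- numeric(length(ks))
  assignments <- vector("list", length(ks))
  for (m in seq_along(ks)) {
    k <- ks[m]
    sel <- if (eig_order == "smallest") rev(seq.int(tsm$p - k + 1L, tsm$p))
           else seq_len(k)
    emb <- structure(list(U = e$vectors[, sel, drop = FALSE],
                          eigenvalues = e$values[sel], eig_order = eig_order),
                     class = "spectral_embedding")
    km_seed <- if (is.null(seed)) NULL else seed + k
    assignments[[m]] <- kmeans_embed(emb, k, n_init = n_init, seed = km_seed)
    mean_s[m] <- .silhouette_from_cov(lc, assignments[[m]]$labels,
                                      shrinkage, var_frac, min_rank)$mean_s
  }
  bp <- detect_breakpoint(ks, mean_s)
  structure(list(ks = ks, mean_s_per_k = mean_s, assignments = assignments,
                 selected_k = bp$selected_k, breakpoint_q = bp$q),
            class = "k_scan")
}

#' @export
print.k_scan <- function(x, ...) {
  cat("k scan (mean cluster index per k):\n")
  print(stats::setNames(round(x$mean_s_per_k, 3), x$ks))
  cat(sprintf("selected k = %d (breakpoint after point %d)\n",
              x$selected_k, x$breakpoint_q))
  invisible(x)
}

#' Write a k-scan table as TSV
#'
#' @param scan A `k_scan`.
#' @param path Output file.
#' @export
write_k_scan <- function(scan, path) {
  stopifnot(inherits(scan, "k_scan"))
  utils::write.table(
    data.frame(k = scan$ks, mean_s = scan$mean_s_per_k,
               selected = scan$ks == scan$selected_k),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
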
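#' Time-series matrix
#'
#' Container for a panel of `p` time series observed at `T` uniformly spaced
#' time points: one row per series (gene), columns ordered by time. This is
#' the universe on which all Granger-causality operations act.
#'
#' @param values Numeric matrix, `p x T`. Rows are series, columns time points.
#' @param series_ids Character vector of unique series identifiers; defaults
#'   to `rownames(values)` or `s1..sp`.
#' @param lag_order Positive integer autoregressive order used by lagged
#'   operations. The implementation targets order 1 (gene-expression series
#'   are short); higher orders are accepted and used as the lag in aligned
#'   windows.
#'
#' @return An object of class `ts_matrix`: a list with elements `values`,
#'   `series_ids`, `lag_order`, `p`, `T`.
#' @examples
#' x <- matrix(rnorm(40), nrow = 4)
#' tsm <- ts_matrix(x)
#' tsm$p
#' @export
ts_matrix <- function(values, series_ids = NULL, lag_order = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  lag_order <- as.integer(lag_order)
  if (lag_order < 1L) stop("lag_order must be a positive integer")
  p <- nrow(values); T_len <- ncol(values)
  if (T_len < lag_order + 3L)
    stop("need at least lag_order + 3 time points, got ", T_len)
  if (is.null(series_ids)) {
    series_ids <- rownames(values)
    if (is.null(series_ids)) series_ids <- paste0("s", seq_len(p))
  }
  series_ids <- as.character(series_ids)
  if (length(series_ids) != p) stop("series_ids length must equal nrow(values)")
  if (anyDuplicated(series_ids))
    stop("duplicated series id: ", series_ids[duplicated(series_ids)][1L])
  if (anyNA(values)) {
    bad <- series_ids[rowSums(is.na(values)) > 0L]
    stop("missing values in series: ", paste(bad, collapse = ", "))
  }
  v <- apply(values, 1L, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    stop("constant series (zero variance): ",
         paste(series_ids[v <= 0 | !is.finite(v)], collapse = ", "))
  }
  rownames(values) <- series_ids
  structure(list(values = values, series_ids = series_ids,
                 lag_order = lag_order, p = p, T = T_len),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("ts_matrix: %d series x %d time points (lag order %d)\n",
              x$p, x$T, x$lag_order))
  invisible(x)
}

#' Standardize each series to mean zero and unit variance
#'
#' CCA-based quantities are invariant to per-series affine rescaling, but
#' standardizing first stabilizes the numerics of covariance inversions and
#' makes PCA retention fractions comparable across series.
#'
#' @param tsm A [ts_matrix].
#' @return A `ts_matrix` whose rows have mean 0 and variance 1.
#' @export
standardize <- function(tsm) {
  stopifnot(inherits(tsm, "ts_matrix"))
  x <- tsm$values
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0)) stop("constant series: ",
                        paste(tsm$series_ids[s == 0], collapse = ", "))
  tsm$values <- (x - rowMeans(x)) / s
  tsm
}

# aligned lag-window covariance cache: 2p x 2p covariance of
# [present (times lag+1..T), lagged (times 1..T-lag)]
.lag_cov <- function(tsm, lag = tsm$lag_order) {
  X <- tsm$values
  T_len <- ncol(X)
  if (T_len - lag < 3L) stop("too few time points for lag ", lag)
  Z <- cbind(t(X[, (lag + 1L):T_len, drop = FALSE]),
             t(X[, 1L:(T_len - lag), drop = FALSE]))
  list(C = stats::cov(Z), p = nrow(X), n_eff = T_len - lag, lag = lag)
}
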
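# ---- data ingestion and export ----------------------------------------------

#' Read an expression matrix from TSV/CSV
#'
#' Expects one row per gene/series: the first column holds the series id, the
#' remaining columns the expression values in time order.
#'
#' @param path File path.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @param log2_transform Apply `log2(x + 1)` to the values after reading.
#' @param lag_order Lag order stored in the returned matrix.
#' @return A [ts_matrix].
#' @export
read_expression_matrix <- function(path, sep = "\t", log2_transform = FALSE,
                                   lag_order = 1L) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stop("need at least 5 time points (plus an id column), got ", ncol(df) - 1L)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated series id: ", ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric values in column ", names(df)[bad + 1L])
  }
  if (anyNA(vals))
    stop("missing values in series: ",
         paste(ids[rowSums(is.na(vals)) > 0L], collapse = ", "))
  if (log2_transform) vals <- log2(vals + 1)
  ts_matrix(vals, series_ids = ids, lag_order = lag_order)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `series_id`, remaining
#' columns `t1..tT`.
#'
#' @param tsm A [ts_matrix].
#' @param path Output file.
#' @export
write_expression_matrix <- function(tsm, path) {
  stopifnot(inherits(tsm, "ts_matrix"))
  df <- data.frame(series_id = tsm$series_ids, tsm$values,
                   check.names = FALSE)
  colnames(df) <- c("series_id", paste0("t", seq_len(tsm$T)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
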
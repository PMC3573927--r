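# ---- Monte-Carlo evaluation harness -----------------------------------------

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) cbind(i, sub + (sub >= i))))
}

#' Clustering accuracy under the best label matching
#'
#' Percentage of series whose cluster label matches the ground truth under
#' the best injective relabeling of the estimated clusters (the optimum of
#' the label-assignment problem), so the value is invariant to cluster
#' numbering. For up to 8 labels the optimum is found by enumeration;
#' beyond that a greedy matching is used.
#'
#' @param labels Estimated integer labels.
#' @param true_labels Ground-truth integer labels of the same length.
#' @return Accuracy in percent (0-100).
#' @examples
#' clustering_accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2))
#' @export
clustering_accuracy <- function(labels, true_labels) {
  labels <- as.integer(labels); true_labels <- as.integer(true_labels)
  if (length(labels) != length(true_labels))
    stop("labels and true_labels must have the same length")
  k <- max(labels, true_labels)
  if (k <= 8L) {
    perms <- .permutations(k)
    best <- 0
    for (r in seq_len(nrow(perms))) {
      acc <- mean(perms[r, labels] == true_labels)
      if (acc > best) best <- acc
    }
  } else {
    tab <- table(factor(labels, 1:k), factor(true_labels, 1:k))
    best <- 0; used <- integer(0)
    for (cl in order(-apply(tab, 1L, max))) {
      cand <- order(-tab[cl, ])
      cand <- cand[!cand %in% used]
      if (length(cand)) { best <- best + tab[cl, cand[1L]]; used <- c(used, cand[1L]) }
    }
    best <- best / length(labels)
  }
  100 * best
}

# map estimated labels onto true ones via the best permutation (k <= 8)
.match_labels <- function(labels, true_labels, k = 4L) {
  perms <- .permutations(k)
  best <- -1; map <- seq_len(k)
  for (r in seq_len(nrow(perms))) {
    acc <- mean(perms[r, labels] == true_labels)
    if (acc > best) { best <- acc; map <- perms[r, ] }
  }
  list(labels = map[labels], accuracy = 100 * best)
}

#' Monte-Carlo experiment on one simulated scenario
#'
#' Repeats, for `n_reps` seeded repetitions of the chosen scenario: simulate
#' the panel, select the number of sub-networks by the breakpoint rule,
#' cluster with the module count fixed at four and score the accuracy, and
#' (on repetitions where the selected number of clusters is correct) infer
#' the cluster-level Granger-causality network and record which directed
#' edges are detected at `alpha`. Aggregates mirror the usual Monte-Carlo
#' summaries: a histogram of selected `k`, the mean and standard deviation
#' of the cluster index at the breakpoint, mean accuracy, and a 4x4
#' edge-detection rate matrix (rows = source module, columns = target).
#'
#' @param scenario Scenario preset 1-4.
#' @param T Time-series length.
#' @param n_reps Number of repetitions.
#' @param seed Base seed; repetition `r` uses `seed * 1000 + r`.
#' @param do_select Run the k scan (breakpoint selection) per repetition.
#' @param do_network Infer the network on repetitions with correctly
#'   selected (or, if `do_select = FALSE`, fixed) `k = 4`.
#' @param k_min,k_max Scan range for the selection step.
#' @param alpha Edge significance level.
#' @param n_init k-means initializations.
#' @return An `experiment_report` list; see the fields in the description.
#' @export
run_scenario_experiment <- function(scenario, T = 200L, n_reps = 10L,
                                    seed = 1L, do_select = TRUE,
                                    do_network = TRUE, k_min = 2L,
                                    k_max = 10L, alpha = 0.05,
                                    n_init = 100L) {
  spec <- scenario_spec(scenario, T = T)
  sel_k <- integer(0); s_bp <- numeric(0); acc <- numeric(0)
  edge_hits <- matrix(0, 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  edge_tries <- 0L
  correct_clustering <- logical(0)
  fp_hits <- 0L; fp_tries <- 0L
  failed <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- seed * 1000L + r
    out <- tryCatch({
      sim <- simulate_scenario(spec, seed = rep_seed)
      res <- list()
      if (do_select) {
        scan <- select_num_clusters(sim$tsm, k_min = k_min, k_max = k_max,
                                    n_init = n_init, seed = rep_seed)
        res$sel_k <- scan$selected_k
        res$s_bp <- scan$mean_s_per_k[scan$breakpoint_q]
        res$assign4 <- if (4L %in% scan$ks)
          scan$assignments[[match(4L, scan$ks)]] else NULL
      }
      if (is.null(res$assign4))
        res$assign4 <- functional_cluster(sim$tsm, 4L, n_init = n_init,
                                          seed = rep_seed + 4L)
      m <- .match_labels(res$assign4$labels, sim$true_labels, 4L)
      res$accuracy <- m$accuracy
      res$mapped <- m$labels
      k_ok <- if (do_select) identical(res$sel_k, 4L) else TRUE
      if (do_network && k_ok) {
        eigs <- extract_eigen_series(sim$tsm, res$mapped)
        net <- infer_network(eigs)
        res$edge_from_to <- net$edges
      }
      res$correct <- res$accuracy == 100
      res
    }, error = function(e) e)
    if (inherits(out, "error")) { failed <- failed + 1L; next }
    if (do_select) { sel_k <- c(sel_k, out$sel_k); s_bp <- c(s_bp, out$s_bp) }
    acc <- c(acc, out$accuracy)
    correct_clustering <- c(correct_clustering, out$correct)
    if (!is.null(out$edge_from_to)) {
      e <- out$edge_from_to
      for (m in seq_len(nrow(e))) {
        fr <- match(e$from[m], as.character(1:4))
        to <- match(e$to[m], as.character(1:4))
        edge_hits[fr, to] <- edge_hits[fr, to] + (e$p_value[m] < alpha)
      }
      edge_tries <- edge_tries + 1L
      if (out$correct) {
        off <- which(e$from != e$to)
        is_true <- .is_true_edge(e$from[off], e$to[off], spec)
        fp_hits <- fp_hits + sum(e$p_value[off][!is_true] < alpha)
        fp_tries <- fp_tries + sum(!is_true)
      }
    }
  }
  structure(list(
    scenario = scenario, T = T, n_reps = n_reps, seed = seed,
    failed = failed,
    k_selection = if (do_select) table(factor(sel_k, levels = 1:12)) else NULL,
    k4_rate = if (do_select) mean(sel_k == 4L) else NA_real_,
    mean_silhouette = if (do_select) mean(s_bp) else NA_real_,
    sd_silhouette = if (do_select) stats::sd(s_bp) else NA_real_,
    mean_accuracy = mean(acc),
    edge_detection = if (edge_tries > 0L) 100 * edge_hits / edge_tries else NULL,
    n_network_reps = edge_tries,
    null_fp_rate = if (fp_tries > 0L) 100 * fp_hits / fp_tries else NA_real_,
    n_null_tests = fp_tries),
    class = "experiment_report")
}

.is_true_edge <- function(from, to, spec) {
  lab <- function(v) LETTERS[as.integer(v)]
  te <- spec$true_edges
  if (is.null(te)) return(rep(FALSE, length(from)))
  paste(lab(from), lab(to)) %in% paste(te$from, te$to)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: scenario %d, T = %d, %d reps (%d failed)\n",
              x$scenario, x$T, x$n_reps, x$failed))
  if (!is.na(x$k4_rate))
    cat(sprintf("  k = 4 selected in %.1f%% of reps; cluster index %.3f (sd %.3f)\n",
                100 * x$k4_rate, x$mean_silhouette, x$sd_silhouette))
  cat(sprintf("  mean accuracy at k = 4: %.1f%%\n", x$mean_accuracy))
  if (!is.null(x$edge_detection)) {
    cat(sprintf("  edge detection rates (%% of %d reps):\n", x$n_network_reps))
    print(round(x$edge_detection, 1))
  }
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param report An `experiment_report`.
#' @param path Output file.
#' @export
write_experiment_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  out <- unclass(report)
  out$k_selection <- as.list(out$k_selection)
  out$edge_detection <- if (!is.null(out$edge_detection))
    as.data.frame(out$edge_detection) else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
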
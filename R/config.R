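# ---- analysis configuration -------------------------------------------------

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with validated defaults:
#' lag order 1 (short expression series), ridge `shrinkage` 0.01, scan range
#' `k_min = 2` to `k_max = 10`, 100 k-means initializations, smallest-eigenvalue
#' spectral embedding, CCA-based Laplacian degrees, a 5% variance-share PCA
#' retention threshold (floor `min_rank` components for set representations),
#' significance levels 0.05/0.10, and the asymptotic test.
#'
#' @param lag_order,shrinkage,k_min,k_max,n_init,eig_order,degree_mode
#'   See [functional_cluster()] and [select_num_clusters()].
#' @param pca_var_frac,min_rank Retention rule for set representations and
#'   eigen-time series.
#' @param alpha_levels Two significance levels for the network stage.
#' @param test_method `"asymptotic"` or `"permutation"`.
#' @param seed Base seed.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(lag_order = 1L, shrinkage = 0.01, k_min = 2L,
                            k_max = 10L, n_init = 100L,
                            eig_order = "smallest",
                            degree_mode = "cca_degree",
                            pca_var_frac = 0.05, min_rank = 5L,
                            alpha_levels = c(0.05, 0.10),
                            test_method = "asymptotic", seed = 1L) {
  cfg <- list(lag_order = as.integer(lag_order), shrinkage = shrinkage,
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              n_init = as.integer(n_init), eig_order = eig_order,
              degree_mode = degree_mode, pca_var_frac = pca_var_frac,
              min_rank = as.integer(min_rank),
              alpha_levels = as.numeric(alpha_levels),
              test_method = test_method, seed = as.integer(seed))
  stopifnot(cfg$lag_order >= 1L, cfg$shrinkage >= 0,
            cfg$k_min >= 2L, cfg$k_max >= cfg$k_min, cfg$n_init >= 1L,
            cfg$eig_order %in% c("smallest", "largest"),
            cfg$degree_mode %in% c("cca_degree", "row_sum"),
            cfg$pca_var_frac > 0, cfg$pca_var_frac < 1, cfg$min_rank >= 1L,
            length(cfg$alpha_levels) == 2L, all(cfg$alpha_levels > 0),
            all(cfg$alpha_levels < 1),
            cfg$test_method %in% c("asymptotic", "permutation"))
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file.
#' @return `read_config` returns a validated `analysis_config`.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg An `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
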
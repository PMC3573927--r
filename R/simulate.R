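# ---- block-VAR(1) simulator of modular regulatory networks ------------------

# latent 20-equation lag-1 coefficient matrices for the four preset network
# topologies: four sub-networks (A: 1-5, B: 6-10, C: 11-15, D: 16-20) with
# beta-weighted within-module terms, plus gamma-weighted cross-module terms
# that differ per preset:
#   1: no cross-module causality
#   2: cycle A -> B -> C -> D -> A
#   3: feedback A <-> B, plus B -> C -> D
#   4: A -> B, A -> C, B -> C, C -> D (A only sends, D only receives)
.latent_coefficients <- function(scenario, beta = 0.6, gamma = 0.3) {
  A <- matrix(0, 20L, 20L)
  set_row <- function(i, js, signs) A[i, js] <<- signs * beta
  set_row(1L, c(1L, 4L, 3L), c(1, -1, 1))
  set_row(2L, c(1L, 3L, 4L), c(1, -1, 1))
  set_row(3L, c(1L, 5L), c(1, -1))
  set_row(4L, c(3L, 5L), c(1, -1))
  set_row(5L, c(2L, 3L, 4L), c(1, -1, 1))
  set_row(6L, c(9L, 7L), c(1, -1))
  set_row(7L, c(10L, 7L), c(1, -1))
  set_row(8L, c(10L, 6L, 7L), c(1, -1, 1))
  set_row(9L, c(7L, 8L, 9L, 6L), c(1, -1, 1, -1))
  set_row(10L, c(10L, 6L, 9L), c(1, -1, 1))
  set_row(11L, c(12L, 15L), c(1, -1))
  set_row(12L, c(14L, 13L), c(1, -1))
  set_row(13L, c(14L, 11L), c(1, -1))
  set_row(14L, c(13L, 11L), c(1, -1))
  set_row(15L, c(15L, 12L, 13L, 14L), c(1, -1, 1, -1))
  set_row(16L, c(19L, 20L, 17L, 18L), c(1, -1, 1, -1))
  set_row(17L, c(20L, 17L, 18L), c(1, -1, 1))
  set_row(18L, c(20L, 18L), c(1, -1))
  set_row(19L, c(17L, 18L), c(1, -1))
  set_row(20L, c(20L, 19L), c(1, -1))
  cross <- switch(as.character(scenario),
    "1" = NULL,
    "2" = rbind(c(3L, 19L), c(6L, 3L), c(14L, 10L), c(20L, 15L)),
    "3" = rbind(c(3L, 6L), c(7L, 3L), c(14L, 10L), c(20L, 15L)),
    "4" = rbind(c(7L, 3L), c(13L, 8L), c(14L, 5L), c(20L, 15L)),
    stop("scenario must be 1, 2, 3 or 4"))
  if (!is.null(cross))
    for (r in seq_len(nrow(cross))) A[cross[r, 1L], cross[r, 2L]] <-
      A[cross[r, 1L], cross[r, 2L]] + gamma
  A
}

.scenario_edges <- function(scenario) {
  switch(as.character(scenario),
    "1" = NULL,
    "2" = data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "A")),
    "3" = data.frame(from = c("A", "B", "B", "C"), to = c("B", "A", "C", "D")),
    "4" = data.frame(from = c("A", "A", "B", "C"), to = c("B", "C", "C", "D")))
}

#' Specification of a simulated modular VAR(1) scenario
#'
#' Describes a Monte-Carlo scenario: 20 latent first-order autoregressive
#' equations organized in four sub-networks (A-D) of five series each, with
#' within-module coefficients of magnitude `beta` and cross-module
#' coefficients `gamma` whose placement depends on the preset topology. Every
#' latent series is expanded into `n_replicates` observed replicate series;
#' the innovation covariance is the Kronecker product of an identity across
#' latent series and a compound-symmetric block with off-diagonal
#' `noise_cor`, so the replicates of one latent series share correlated noise
#' while different latent series have independent innovations.
#'
#' @param scenario Preset topology, 1-4: 1 = independent modules, 2 = cycle
#'   A-B-C-D-A, 3 = feedback loop between A and B (plus B-C, C-D),
#'   4 = sender/receiver (A only sends, D only receives).
#' @param T Number of retained time points.
#' @param beta,gamma Within- and cross-module coefficient magnitudes.
#' @param n_replicates Observed replicate series per latent series.
#' @param noise_cor Innovation correlation among replicates of one latent
#'   series.
#' @param burn_in Initial iterations discarded before recording.
#' @return A `scenario_spec` list; pass to [simulate_scenario()].
#' @examples
#' spec <- scenario_spec(2, T = 100)
#' dim(build_coefficient_matrix(spec))
#' @export
scenario_spec <- function(scenario = 1L, T = 200L, beta = 0.6, gamma = 0.3,
                          n_replicates = 10L, noise_cor = 0.6,
                          burn_in = 500L) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  structure(list(scenario = scenario, T = as.integer(T), beta = beta,
                 gamma = gamma, n_replicates = as.integer(n_replicates),
                 noise_cor = noise_cor, burn_in = as.integer(burn_in),
                 latent = .latent_coefficients(scenario, beta, gamma),
                 blocks = rep(c("A", "B", "C", "D"), each = 5L),
                 true_edges = .scenario_edges(scenario)),
            class = "scenario_spec")
}

#' Replicate-expanded lag-1 coefficient matrix
#'
#' Expands the latent coefficient matrix to the observed dimension: each
#' latent coefficient acts replicate-wise, i.e. replicate `r` of a target
#' depends on replicate `r` of each source (an identity block scaled by the
#' signed coefficient). Rows are ordered latent-major: the `n_replicates`
#' replicates of latent series 1 first, and so on.
#'
#' @param spec A `scenario_spec`.
#' @return A `(20 * n_replicates)` square matrix.
#' @export
build_coefficient_matrix <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  spec$latent %x% diag(spec$n_replicates)
}

#' Simulate a modular VAR(1) scenario
#'
#' Draws Gaussian innovations with the Kronecker covariance, iterates the
#' replicate-expanded VAR(1) from a zero state, discards the burn-in, and
#' returns the observed panel together with the ground truth. The spectral
#' radius of the coefficient matrix is checked first; a non-stationary
#' specification is refused.
#'
#' @param spec A `scenario_spec`.
#' @param seed Integer seed (required for reproducibility).
#' @return A `simulation_output`: list with `tsm` (a [ts_matrix] with ids
#'   like `A1.r1 .. D20.r10`), `true_labels` (integer module memberships,
#'   four groups), and `true_edges` (directed cross-module edges of the
#'   preset, or `NULL`).
#' @examples
#' sim <- simulate_scenario(scenario_spec(1, T = 50), seed = 7)
#' sim$tsm
#' @export
simulate_scenario <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (missing(seed)) stop("a seed is required")
  rho <- max(Mod(eigen(spec$latent, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("non-stationary specification (spectral radius %.3f >= 1)", rho))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  nrep <- spec$n_replicates
  n_lat <- nrow(spec$latent)
  p <- n_lat * nrep
  A <- build_coefficient_matrix(spec)
  G <- matrix(spec$noise_cor, nrep, nrep); diag(G) <- 1
  Lg <- chol(G)                      # t(Lg) %*% z gives correlated replicates
  steps <- spec$burn_in + spec$T
  X <- matrix(0, p, steps)
  x <- numeric(p)
  for (t in seq_len(steps)) {
    Z <- matrix(stats::rnorm(p), nrep, n_lat)
    eps <- as.vector(crossprod(Lg, Z))
    x <- drop(A %*% x) + eps
    X[, t] <- x
  }
  X <- X[, (spec$burn_in + 1L):steps, drop = FALSE]
  ids <- paste0(rep(spec$blocks, each = nrep),
                rep(seq_len(n_lat), each = nrep), ".r", seq_len(nrep))
  labels <- rep(rep(1:4, each = 5L), each = nrep)
  structure(list(tsm = ts_matrix(X, series_ids = ids),
                 true_labels = labels, true_edges = spec$true_edges,
                 spec = spec, seed = seed),
            class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf("simulation_output: scenario %d, %d series x %d points (seed %d)\n",
              x$spec$scenario, x$tsm$p, x$tsm$T, x$seed))
  invisible(x)
}
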
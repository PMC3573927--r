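# grangerclust

Functional clustering of time-series gene-expression data by Granger
causality, with cluster-number selection and cluster-level causal network
inference.

## What problem this solves

Clustering time-course expression data by waveform similarity groups genes
that *look* alike. Genes in the same regulatory module, however, need not be
correlated — they are connected by *information flow*: the past of one
improves prediction of another. `grangerclust` clusters series by their
topological proximity in that flow network, for analysts who want modules
defined by regulatory interaction rather than profile shape, and then infers
the directed Granger-causality network *between* the modules.

## The method in brief

Granger causality between sets of series is measured by canonical
correlation analysis (CCA) of lagged blocks in a first-order VAR setting.
The building blocks:

* distance `d(i,j) = 1 − (|CCA(xᵢ,t , xⱼ,t−1)| + |CCA(xⱼ,t , xᵢ,t−1)|) / 2`,
  symmetric, in [0, 1];
* similarity graph `W = 1 − d` with Laplacian `L = D − W`, where `D` carries
  each series' Granger-causality degree (CCA with the lagged remainder of
  the network);
* spectral clustering: k-means (100 seeded restarts) on the eigenvectors of
  the smallest Laplacian eigenvalues;
* number of clusters: a silhouette-type index
  `s(i) = (b(i) − a(i)) / max(a(i), b(i))` built from set-level CCA
  distances, scanned over k = 2..10, with the drop located by a two-segment
  least-squares breakpoint fit;
* cluster network: per-cluster eigen-time series (PCA components with > 5%
  of the temporal variance), then for every ordered pair j → i the partial
  CCA of cluster i at t on cluster j at t−1 given all other clusters' past,
  tested with the Bartlett–Lawley chi-square statistic (a circular-shift
  permutation test is available).

A built-in simulator generates the four benchmark topologies used to
validate the method: 20 latent VAR(1) equations in four modules (β = 0.6,
cross-module γ = 0.3), each latent series expanded to 10 replicates with
innovation correlation 0.6 (Kronecker covariance I₂₀ ⊗ Γ), i.e. 200 observed
series.

## Worked example

Simulate the cyclic scenario (modules A→B→C→D→A), pick the number of
modules, cluster, and infer the module network:

```r
library(grangerclust)

spec <- scenario_spec(2, T = 200)          # cyclic topology
sim  <- simulate_scenario(spec, seed = 2)

scan <- select_num_clusters(sim$tsm, seed = 2)
scan
#> k scan (mean cluster index per k):
#>     2     3     4     5     6     7     8     9    10
#> 0.466 0.491 0.495 0.435 0.387 0.293 0.221 0.208 0.190
#> selected k = 4 (breakpoint after point 3)

cl <- scan$assignments[[match(4, scan$ks)]]
clustering_accuracy(cl$labels, sim$true_labels)
#> [1] 99.5

eigs <- extract_eigen_series(sim$tsm, cl$labels)
net  <- infer_network(eigs)
subset(net$edges, significant_0.05)
#>  from to rho_hat   p_value significant_0.05 significant_0.10
#>     1  1   0.927 1.75e-120             TRUE             TRUE
#>     1  3   0.416  6.37e-06             TRUE             TRUE
#>     2  2   0.896 5.01e-134             TRUE             TRUE
#>     2  4   0.411  5.03e-04             TRUE             TRUE
#>     3  1   0.266  3.28e-02             TRUE             TRUE
#>     3  2   0.388  9.88e-04             TRUE             TRUE
#>     3  3   0.896 1.21e-109             TRUE             TRUE
#>     3  4   0.312  4.41e-02             TRUE             TRUE
#>     4  1   0.414  1.44e-05             TRUE             TRUE
#>     4  4   0.912 4.75e-157             TRUE             TRUE
```

Reading the output: the cluster index stays level up to k = 4 and drops
afterwards, so the breakpoint rule selects four modules; 199 of 200 series
are assigned to their true module. In this run the estimated clusters 2, 4,
1, 3 correspond to true modules A, B, C, D, so the significant off-diagonal
edges 2→4, 4→1, 1→3, 3→2 recover the planted cycle A→B→C→D→A (the diagonal
entries are each module's own dynamics; the two weakest extra edges at
p ≈ 0.03–0.04 trace back to the single misassigned series).

The same pipeline runs from the shell:

```sh
Rscript inst/cli/grangerclust.R simulate --scenario 2 --T 200 --seed 2 \
    --out matrix.tsv --labels truth.tsv
Rscript inst/cli/grangerclust.R select-k --in matrix.tsv --seed 2 \
    --out kscan.tsv --labels labels.tsv
Rscript inst/cli/grangerclust.R network --in matrix.tsv --labels labels.tsv \
    --out edges.tsv
```

For real data, `read_expression_matrix()` ingests a genes × time-points
TSV/CSV (first column gene ids; uniform sampling assumed, normalization done
upstream).

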
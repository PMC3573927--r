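Package: grangerclust
Title: Functional Clustering of Time Series by Granger Causality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters gene-expression time series by their topological
    proximity in a regulatory network rather than by waveform similarity.
    Granger causality between series (and between sets of series) is
    quantified through lagged and partial canonical correlation analysis
    (CCA), turned into a symmetric distance, and fed to a spectral
    clustering algorithm on the resulting similarity graph. The number of
    sub-networks is chosen by a silhouette-type cluster index combined
    with a two-segment breakpoint regression, and a cluster-level
    Granger-causality network is inferred from per-cluster eigen-time
    series with asymptotic or permutation tests. Includes a block-VAR(1)
    simulator of modular regulatory networks with correlated replicate
    expansion, and an evaluation harness for Monte-Carlo experiments on
    cluster-number selection, clustering accuracy and edge detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
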
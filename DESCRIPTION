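Package: netcentral
Title: Density-Integrated Centrality Analysis of Structural Connectomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for graph-theoretic centrality analysis of structural
    brain connectomes built from probabilistic-tractography streamline
    counts. Raw asymmetric count matrices are waytotal-normalized,
    symmetrized and proportionally thresholded across a range of network
    densities; node degree and betweenness centrality are computed at each
    density and integrated (summed) across the sweep to one value per
    region. An inferential layer provides two-sample permutation t-tests,
    Cohen's d, Spearman rank correlations, covariate adjustment by
    ordinary least squares, and Benjamini-Hochberg false-discovery-rate
    control, orchestrated into primary region-of-interest tests,
    whole-network exploratory scans and a surgical-outcome subanalysis.
    A synthetic cohort generator produces streamline-count connectomes
    and clinical covariate tables with a plantable group effect on one
    node's centrality and a rank-coupled disease-duration covariate, so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
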
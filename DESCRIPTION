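Package: mstnet
Title: Minimum Spanning Tree Analysis of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for minimum-spanning-tree (MST) analysis of functional
    connectivity networks. Builds Fisher-z connectivity from ROI time series,
    extracts the MST with Kruskal's algorithm after negative-edge removal,
    computes global tree metrics (path length, leaf fraction, tree hierarchy,
    maximum degree, assortativity, degree divergence) and nodal metrics
    (betweenness, local importance, connector index) with hub/connector
    classification, quantifies between-subject tree similarity by edge
    overlap with a within-group permutation test, fits MST degree
    distributions (power law, exponential, exponentially truncated power
    law), performs covariate-adjusted permutation group tests with FDR
    correction and age/gender cohort matching, and estimates
    age - network integration - symptom mediation and moderation models with
    bootstrap confidence intervals. Includes a synthetic-cohort generator
    with planted tree topology and mediation structure for end-to-end
    validation without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    clue
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    xml2
Config/testthat/edition: 3
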
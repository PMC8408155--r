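Package: gdism
Title: Machine-Learned Network Dismantling and Early-Warning Signals of
    Collapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a graph-attention node-scoring model on small synthetic
    networks that are dismantled optimally by exhaustive enumeration, and
    uses the learned scores to dismantle arbitrary undirected networks via
    a static ranked attack with greedy node reinsertion. Provides the
    dismantling robustness metric (Simpson-rule area under the largest
    connected component curve), heuristic baseline attacks, articulation
    point traces, and an early-warning statistic that predicts systemic
    collapse from the cumulative score of removed nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
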
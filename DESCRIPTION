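Package: tdgrn
Title: Time-Delayed Gene Regulatory Network Inference with
    Complex-Valued Flexible Neural Trees
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed, lag-annotated gene regulatory networks from
    short gene-expression time courses. For each target gene, candidate
    regulators are shortlisted by a hybrid rank aggregation of three
    time-delayed association measures (time-delayed mutual information,
    time-delayed maximal information coefficient and time-delayed Pearson
    correlation), a lag-aligned design matrix is assembled at the optimal
    per-pair lags, and a complex-valued flexible neural tree is fitted by
    genetic-programming structure search with bat-algorithm parameter
    optimisation; regulators are read off the fitted tree. Includes a
    synthetic time-course generator with known ground-truth networks,
    directed-edge confusion/metric evaluation, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: NetworkInference, GeneRegulation, TimeCourse, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'delay.R'
    'inference.R'
    'io.R'
    'methods-accessors.R'
    'optimize.R'
    'scoring.R'
    'simulate.R'
    'tdgrn-package.R'
    'tree.R'
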
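Package: hrgnet
Title: Hierarchical Random Graph Rescoring of Bootstrap Gene Network Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Extracts a maximum-likelihood hierarchical random graph model
    from an ensemble of bootstrap-inferred gene regulatory networks by
    simulated annealing over rooted binary dendrograms, and uses the fitted
    hierarchy to re-score regulation confidences. Includes an S-system
    time-series simulator for generating synthetic expression data, a
    pluggable baseline bootstrap inference stage, and recall-precision
    (AURPC) evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, deSolve, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), ape, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
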
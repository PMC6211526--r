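Package: picksieve
Title: Consensus-Driven Particle Pruning for Cryo-EM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic pruning of single-particle cryo-EM picking results by
    consensus of multiple particle pickers. Coordinates agreed on by all
    pickers (the AND set) and random far-from-any-pick positions (the NEG set)
    form positive and negative training labels for a convolutional neural
    network, which then scores the union of all picks (the OR set) so that
    low-scoring false positives can be removed. Includes MRC2014 micrograph
    and particle-stack input/output, TSV/BOX/STAR coordinate dialects, a CPU
    implementation of the classifier with Adam training and plateau learning
    rate decay, a synthetic micrograph and picker simulator for end-to-end
    validation, and a label-noise robustness experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph
SystemRequirements: C++17
Config/testthat/edition: 3
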
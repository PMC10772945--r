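Package: nanosieve
Title: Raw-Signal Classification and Simulated Adaptive Sampling for
    Nanopore Host Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for depleting host DNA during nanopore sequencing by
    classifying raw current signals (squiggles). Provides a k-mer
    pore-model squiggle simulator with ground-truth base-to-sample maps,
    a 1D convolutional network with squeeze-and-excitation channel
    attention trained directly on normalized signal chunks, 5-fold and
    leave-one-species-out cross-validation, a simulated Read-Until
    adaptive-sampling loop with enrichment statistics, and 6-mer
    composition and per-k-mer signal analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    jsonlite,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
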
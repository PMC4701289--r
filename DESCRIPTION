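Package: fbgchew
Title: Classification of Ruminant Chewing Patterns from Fiber Bragg Grating
    Jaw-Strain Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and supervised classification of ruminant ingestive
    behavior from jaw-bone strain measured by a fiber Bragg grating (FBG)
    sensor. Provides a class-conditional waveform simulator for chewing
    sessions (dietary supplement, hay, ryegrass, rumination and idleness),
    per-second mean detrending with zero-crossing chew segmentation,
    construction of fixed-length time plus harmonic-magnitude feature
    vectors, a from-scratch C4.5 decision-tree learner with gain-ratio
    splitting and pessimistic error-based post-pruning, rule extraction,
    and stratified k-fold cross-validated evaluation with confusion-matrix
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
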
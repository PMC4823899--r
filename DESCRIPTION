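Package: ucatest
Title: Model-Selection and Permutation Tests of Common Ancestry for
    Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing phylogenetic tests of common ancestry.
    Simulates amino-acid sequence sets under explicit common-ancestry and
    independent-origins scenarios (star trees with saturated branches,
    per-column profile sampling, two-group quartet scenarios with indels),
    runs the AIC/BIC model-selection test that compares one tree for all
    sequences against separate trees per group, provides a progressive
    multiple aligner and identity statistics, and implements a frequentist
    column-permutation test with tree-length and identity-difference
    statistics.  Scripted experiments reproduce the failure modes of the
    model-selection test at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
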
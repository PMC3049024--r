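Package: dogphy
Title: Discrete Orthologue Groups and Phylogenomic Intersection Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profile-based identification of discrete orthologue
    groups (DOGs) across proteomes, construction of binary detection and
    concatenated amino-acid character matrices, likelihood and Bayesian
    phylogenetics under binary restriction and empirical amino-acid models
    (discrete-gamma rate variation, covarion switching), and interrogation
    of where a constrained monophyletic outgroup intersects a fixed host
    topology via log10 Bayes factors, Shimodaira-Hasegawa and approximately
    unbiased topology tests, quartet support and compositional diagnostics.
    Includes a synthetic-data module that simulates species trees, gene
    gain/loss, proteomes and intersection datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
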
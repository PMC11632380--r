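Package: convsel
Title: Convergent Selection Analysis for Binary Traits on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects convergent shifts in molecular evolution associated with a
    binary species trait (for example the loss of prepupal diapause in bees).
    Computes relative evolutionary rates from per-orthogroup gene trees,
    correlates them with foreground species on terminal branches, and
    calibrates significance with a phylogenetically constrained permutation
    ("permulation") null. Provides simplified codon-model likelihood-ratio
    tests for relaxed or intensified selection (selection intensity K) and for
    episodic positive selection on foreground branches, an evidence-combination
    classifier with term and gene-list enrichment, orthogroup and gene-family
    filtering rules, binary-trait phylogenetic generalized least squares,
    reciprocal-best-hit joining, and a fully seeded synthetic-data generator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
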
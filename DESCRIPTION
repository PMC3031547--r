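Package: alnsens
Title: Alignment Sensitivity Analysis for Widely Divergent Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the choice of multiple sequence alignment
    method propagates into downstream evolutionary inference for highly
    divergent protein families such as insect odorant binding proteins
    (~20% pairwise identity, six conserved cysteine anchors, lineage-specific
    expansions). Provides a codon-level gene-family simulator with known
    truth (tree, alignment, per-site selective regime), a battery of
    progressive aligner presets plus ingestion of external alignments,
    per-alignment statistics (core length, percent identity,
    parsimony-informative sites, column congruence, an entropy-based
    substitution-saturation index), maximum-likelihood phylogenetics under
    LG+I+Gamma (BioNJ, NNI search, nonparametric bootstrap, midpoint
    rooting), Robinson-Foulds concordance and method ranking, and
    Goldman-Yang codon models of positive selection (M0, M1a, M2a, M7, M8,
    branch and branch-site tests, likelihood-ratio tests, empirical-Bayes
    site identification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
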
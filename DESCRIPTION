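Package: chlorophylo
Title: Data Requirements for Chloroplast Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking how much chloroplast genome data a
    phylogenetic question needs. Provides a compact maximum-likelihood
    engine for nucleotide alignments (GTR substitution model with
    discrete-gamma rate heterogeneity, Felsenstein pruning, branch-length
    and model optimization, randomized maximum-parsimony starting trees
    and NNI hill climbing), per-gene relative evolutionary rates measured
    as gene tree length over concatenated tree length, rate-category
    partitioning of genes, non-parametric bootstrap subsampling
    experiments that trace bipartition support as a function of alignment
    size, descriptive alignment statistics (variable and
    parsimony-informative sites), a plastid genome-content comparison, and
    a simulator of multi-gene chloroplast-like datasets with known trees
    and per-gene rate multipliers for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
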
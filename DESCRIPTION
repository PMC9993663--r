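Package: markotax
Title: Alignment-Free Taxonomic Classification of Metagenomic Reads with
    Genome Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds fixed-order Markov models of microbial genomes on the
    fly and scores shotgun metagenomic reads by log-likelihood, without
    alignment. Genomes are segmented into compositionally homogeneous
    regions with a Markovian Jensen-Shannon divergence criterion and the
    segments are clustered to build calibration training pools; raw read
    scores are converted into per-rank assignment probabilities with
    cross-validated logistic regression, thresholded at a probability
    cutoff, and optionally merged with the output of a first-pass exact
    k-mer classifier so that only its unclassified reads are
    re-classified. Includes a mosaic-genome and shotgun-read simulator
    and per-rank sensitivity/precision benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp (>= 1.0.0),
    glmnet,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
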
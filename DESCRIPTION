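Package: cnvrassoc
Title: Case-Control Association Analysis of SNP-Array Copy Number Variant Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genome-wide case-control
    studies of copy number variation (CNV) called from SNP-array intensity
    data. Generates synthetic cohorts of per-marker LogR-ratio (LRR) and
    B-allele-frequency (BAF) tracks with implanted deletion and duplication
    loci, calls CNVs with three independent callers (a hidden-Markov-model
    caller, a Bayes-factor caller and a Gaussian-partition caller) sharing
    one emission model, applies sample- and call-level quality control,
    exclusion-region filtering and adjacent-call merging, builds multi-caller
    consensus calls and innermost-boundary CNV regions (CNVRs), and runs
    permutation burden tests, two-tailed Fisher-exact association with
    Benjamini-Hochberg FDR control, Fisher's combined probability
    meta-analysis, gene-set overrepresentation, pathway enrichment
    permutation tests and expression-percentile selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
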
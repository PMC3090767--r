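Package: diffsubnet
Title: Differentially Abundant Metabolic Subnetworks from Metagenomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies connected metabolic subnetworks (sets of reactions)
    that are differentially abundant between two groups of metagenomic
    samples. Per-reaction differential abundance is assessed with a
    Welch-t permutation test on relative abundances and converted to signed
    Z-scores; a greedy maximum-weight search over the edge-weighted
    metabolic network proposes candidate subnetworks, in arbitrary-subgraph
    or reaction-chain mode. Each candidate receives two complementary
    permutation p-values: one from permuting sample labels (differential
    abundance) and one from permuting edge weights across the network
    (topology-induced selection bias). Includes readers for edge-list,
    abundance, group and BLAST tabular files, a planted-signal simulator
    matching a Gaussian relative-abundance model, and ROC benchmarking
    utilities against per-reaction and pathway-aggregate baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
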
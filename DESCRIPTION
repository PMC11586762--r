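Package: burdenMC
Title: Empirical Rare-Variant Burden Testing Against Simulated Control Cohorts
Version: 0.9.0
Authors@R:
    person("burdenMC", "Maintainers", email = "maintainers@burdenmc.dev",
           role = c("aut", "cre"))
Description: Monte-Carlo gene burden testing for small, ancestrally
    heterogeneous sequencing cohorts. Control cohorts are simulated from
    population allele-count summary statistics (gnomAD-style AC/AN tables) by
    per-variant hypergeometric sampling, yielding empirical per-ancestry and
    combined burden p-values. Includes the reciprocal variant-filtering stack
    (population-, complexity- and cohort-derived filters), symmetric DUST
    low-complexity masking, LD pruning from co-occurrence counts, ancestry
    assignment by principal-component projection and random-forest
    classification, collapsed-marker effect-size estimation, replication
    permutation testing, missense tolerance ratio profiling, and a synthetic
    data generator so the whole framework is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
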
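Package: steppescan
Title: Selection Scans and Population Structure for SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Haplotype-based (EHH, iHS, XP-EHH) and allele-frequency-based
    (Hudson F_ST, population branch statistic, multiple-regression
    divergence score) genome scans for recent positive selection, with
    200-kb region aggregation, empirical p-values, cross-population
    candidate overlap testing, and a hemoglobin genotype-phenotype
    association stage.  Includes population-structure utilities (LD
    pruning, allele-sharing distances, classical PCA, neighbor-joining
    trees) and a seed-deterministic synthetic-data generator
    (Balding-Nichols allele frequencies, forward Wright-Fisher
    haplotype simulation with selective sweeps, phenotype simulation)
    so that every stage of the pipeline is testable without external
    genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
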
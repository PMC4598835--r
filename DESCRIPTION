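Package: pcoscausal
Title: Case-Control GWAS, Mendelian Randomization and Selection Tests for
    Polycystic Ovary Syndrome Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for a case-control genome-wide association
    analysis of polycystic ovary syndrome and its downstream causal and
    evolutionary inference: additive-model logistic association with genomic
    control, fixed-effect inverse-variance meta-analysis with Cochran's Q
    heterogeneity, weighted-allele-score Mendelian randomization calibrated
    to 1-s.d. exposure units with per-SNP sensitivity diagnostics, tests for
    positive and polygenic selection (region-overlap binomial test, Qx with
    frequency-matched bootstrap null, iHS, DIND), and permutation-based
    gene-set enrichment of GWAS results. Includes seeded generators for
    synthetic cohorts, multi-population allele-frequency panels and
    Wright-Fisher haplotypes so every stage can be exercised and calibrated
    without access to individual-level cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
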
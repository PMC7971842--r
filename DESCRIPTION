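Package: poescan
Title: Parent-of-Origin Effect Scans from Case-Parent Trio Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Log-linear modelling of parent-of-origin (imprinting) effects in
    case-parent family genotype data. Reads pedigree-format (PED/MAP) files,
    applies per-SNP quality control (no-call rate, trio Mendelian-error rate,
    minor allele frequency, exact Hardy-Weinberg tests within population
    strata), fits a multinomial log-linear likelihood over case-trio genotype
    categories with mating-type stratification, child and maternal genotype
    relative risks and a parent-of-origin relative risk, marginalising over
    missing parents, and runs Bonferroni-corrected multi-SNP scans with
    likelihood-ratio p-values and Wald confidence intervals. Includes a
    synthetic case-family generator for ascertained trios under the same
    model, so every stage is testable without access to restricted study
    genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
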
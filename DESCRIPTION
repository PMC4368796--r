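Package: poefam
Title: Parent-of-Origin Effect Association Analysis in Family Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Family-based tests for parent-of-origin effects (POE) on a
    quantitative trait and on disease risk. Provides PLINK-dialect
    pedigree/genotype/phenotype input, SNP-level quality control (call
    rate, exact Hardy-Weinberg test, minor allele frequency),
    deterministic Mendelian constraint-propagation phasing that assigns
    parental origin to alleles through a pedigree, standard/paternal/
    maternal allelic regression on a log-transformed trait with covariate
    adjustment, comparison of paternal and maternal effect sizes, the
    parental asymmetry test (PAT) for case-parent trios, pairwise
    haplotype linkage-disequilibrium r-squared, and a gene-dropping
    simulator with stored transmission truth for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
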
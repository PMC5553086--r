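Package: wpair
Title: W-Test and Comparator Tests for Pairwise SNP-SNP Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise two-locus association testing for case/control
    genotype data. Implements the W-test, a scaled chi-squared statistic
    built from per-genotype-category normalized log odds ratios with
    scale and degrees-of-freedom parameters supplied by default formulas
    or estimated by a null-phenotype bootstrap, alongside the standard
    comparator battery: Pearson chi-squared tests on the full and reduced
    genotype-combination table and likelihood-ratio logistic regression
    tests with genotypic or allelic codings. Includes a two-locus
    case/control simulator with configurable minor allele frequencies,
    haplotype-level linkage disequilibrium calibrated to a target
    r-squared, and logit-linear or tabular penetrance models, plus
    replicate-loop benchmarking of type-I error and power under the two
    conventions for accounting undefined test results, Q-Q diagnostics
    and genomic-control lambda. Reads PLINK-style text genotype formats.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
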
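Package: poolGWAS
Title: Pooled-Sample GWAS Allelotyping, Monte Carlo Ranking and Replication
    Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-stage pooled-DNA genome-wide association studies.
    The discovery stage estimates group allele frequencies from allele-specific
    probe fluorescence of DNA pools hybridized to a SNP array, screens SNPs by
    the mean and coefficient of variation of the four case/control frequency
    ratios formed from duplicate pools, and ranks candidates with a Monte Carlo
    empirical null of the (mean, CV) pair. The replication stage computes
    case-control association statistics from individual genotypes: genotypic
    Pearson chi-square, oriented allelic odds ratios with Woolf confidence
    intervals, Hardy-Weinberg equilibrium checks in controls, and Breslow-Day
    heterogeneity across stages. A synthetic-cohort generator emulates the
    pooled design (Hardy-Weinberg genotypes, DNA pools in biological
    duplicate, noisy probe intensities, planted risk alleles) so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
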
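Package: triotmt
Title: Randomization-Based Causal Tests for Parent-Child Trio Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the transmission mean test (TMT) and the
    transmission disequilibrium test (TDT) as randomization-based causal
    tests of genotype-phenotype effects in parent-child trios. Mendelian
    transmission from heterozygous parents randomizes the allele a child
    receives, so within-trio transmissions act as a natural experiment:
    the package derives per-trio control/treatment assignments from
    unphased biallelic genotypes, estimates the average causal effect of
    the transmitted allele with an unbiased centered estimator, and tests
    it against a Normal(0,1) or permutation null. A structured-population
    trio simulator (admixture with Balding-Nichols differentiation,
    Mendelian transmission, quantitative/binary/confounded trait models,
    two-locus linkage) and an evaluation harness (type-I error, ROC,
    p-value uniformity, confounding contrasts against per-locus OLS)
    support calibration studies. Reads VCF + PLINK .fam trio data and
    plain genotype-matrix fixtures.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
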
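Package: beanrhm
Title: Regional Heritability Mapping and Mixed-Model GWAS for Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage variance-component QTL mapping for diversity panels of
    inbred lines genotyped with mixed codominant (SNP) and dominant
    presence/absence (DArT) markers. Stage one fits the augmented-block
    mixed model by REML, producing deregressed genotypic values and the
    genetic-parameter summary (joint heritability, genotype-by-environment
    coefficient, across-site genetic correlation). Stage two builds
    allele-frequency-scaled genomic relationship matrices, runs a
    kinship-corrected single-marker association scan and a sliding-window
    regional heritability scan with likelihood-ratio tests and seeded
    permutation significance thresholds. Includes linkage-disequilibrium
    decay estimation with structure and relatedness correction, and a
    seeded generator of synthetic two-gene-pool inbred panels and
    augmented-block field trials for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
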
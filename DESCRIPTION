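Package: compg
Title: Compound-Genotype Pairwise SNP Interaction Analysis for Case-Control Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pairwise SNP-SNP interactions in case-control
    genetic association panels through compound genotypes: a four-level factor
    built from two dominant-coded variants. Provides per-cohort quality control
    (minor allele frequency, exact Hardy-Weinberg test, missingness, imputation
    quality) and greedy linkage-disequilibrium pruning; dominant-model logistic
    fits for single SNPs, compound genotypes, and multiplicative interactions
    with age, sex, and APOE epsilon-2/epsilon-4 covariate adjustment and an
    optional family random intercept; fixed-effects inverse-variance
    meta-analysis with Benjamini-Hochberg false-discovery-rate control;
    one-degree-of-freedom chi-square contrasts between coefficient estimates,
    partial-interaction detection, and SNP-pair classification; Fisher-z tests
    of case/control linkage-disequilibrium differences; and a latent-Gaussian
    multi-cohort genotype/phenotype simulator with tetrachoric calibration of
    target allelic correlations, so that every pipeline stage is testable
    without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    sandwich,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
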
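Package: cismr
Title: Drug-Target cis-Mendelian Randomisation with Correlated Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for drug-target cis-Mendelian randomisation
    from genome-wide association study (GWAS) summary statistics: cis-region
    and significance filtering of instruments, p-value-priority linkage
    disequilibrium (LD) clumping, allele harmonisation of exposure, outcome,
    mediator and LD matrix, the correlated-variant inverse-variance weighted
    (IVW) estimator (generalised least squares with an LD correlation
    matrix) and its uncorrelated special case, dose scaling of odds ratios,
    leave-one-out re-estimation, two-step cis-MR mediation adjustment, and a
    sex-stratified individual-level stage with per-variant covariate-adjusted
    logistic regressions. Includes a synthetic-data generator (Gaussian-copula
    genotypes with controllable LD, phenotypes under a known causal effect,
    two-sample summary statistics and a biobank-like cohort) so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
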
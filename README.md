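# cismr

Drug-target cis-Mendelian randomisation (MR) from GWAS summary statistics,
with correlated instruments.

`cismr` is built for the question "would pharmacologically inhibiting this
protein change disease risk?", answered genetically: variants in or near
the gene encoding the drug target (cis-variants) proxy lifelong target
perturbation through a surrogate biomarker. The motivating analysis is
PDE5 inhibition (sildenafil's target), proxied by diastolic blood pressure
(DBP) via five variants at the PDE5A locus, against Alzheimer's disease
(AD) risk. Everything is reusable for other targets: the package takes
plain summary-statistics tables, an LD matrix, and (optionally) an
individual-level cohort.

## What it computes

The causal log-odds of outcome per 1 mmHg of exposure, from per-variant
exposure effects `bx` and outcome effects `by` with outcome standard
errors `sy` and an LD correlation matrix `rho`, by generalised least
squares (the correlated-variant inverse-variance weighted estimator):

    theta_hat = (bx' O^-1 bx)^-1 bx' O^-1 by,   O_jk = sy_j sy_k rho_jk
    se(theta_hat) = sqrt((bx' O^-1 bx)^-1)

Estimates are reported as an odds ratio per 5.5 mmHg *decrease* in DBP —
the effect of a daily 100 mg sildenafil dose — via
`OR = exp(-5.5 * theta_hat)`.

Around that core the package provides the full pipeline:

* **Instrument selection** — cis-region and significance filtering, greedy
  p-value-priority LD clumping (`r^2 < 0.35`, 10,000 kb window), per-variant
  F-statistics.
* **Harmonisation** — allele alignment of exposure, outcome, mediator and
  LD matrix, with strand relabelling, palindromic-variant policy, and a
  complete exclusion/flip audit trail.
* **Sensitivity analyses** — leave-one-out re-estimation, the uncorrelated
  (pQTL) special case, and two-step cis-MR: subtracting a mediated path
  (e.g. variant → BMI → AD) from the outcome associations with propagated
  uncertainty before re-estimating.
* **Sex-stratified individual-level stage** — per-variant logistic
  regressions of AD status on dosage with age, genotyping batch and 10
  genetic principal components as covariates, fitted separately by sex and
  fed into the same IVW machinery.
* **Synthetic data** — a Gaussian-copula genotype generator with
  controllable LD, phenotypes under a known causal effect, two-sample
  summary statistics from disjoint cohorts, and a biobank-like cohort with
  dementia-subtype labels, so every stage is testable offline.

## Worked example

The canonical five DBP instruments ship with the package; the outcome
associations below are a *synthetic* stand-in (simulated under a null
causal effect at the main AD GWAS's sample size — no real per-variant AD
associations are redistributed here), as is the LD matrix.

```r
library(cismr)

x  <- read_summary_stats(system.file("extdata", "pde5_dbp_instruments.tsv",
                                     package = "cismr"))
y  <- read_summary_stats(system.file("extdata", "synthetic_ad_outcome.tsv",
                                     package = "cismr"))
ld <- read_ld_matrix(system.file("extdata", "synthetic_pde5_ld.tsv",
                                 package = "cismr"),
                     ref_alleles = setNames(x$effect_allele, x$rsid))

iset <- clump(x, ld, r2_threshold = 0.35, window_kb = 10000)
h    <- harmonise(iset$variants, y, iset$ld)
scale_estimate(mr_ivw_correlated(h), 5.5)
#> MR estimate [ivw_correlated]
#>   theta  = 0.000840102 (SE 0.0392215) per unit exposure
#>   95% CI = [-0.0760325, 0.0777127], p = 0.983, n_snps = 5
#>   OR per 5.5-unit decrease = 0.9954 [0.6522, 1.519]
```

Read: per 1 mmHg of DBP the log-odds of AD changes by 0.0008 (indistinguishable
from zero, as it should be — the outcome fixture was generated under the
null), and re-expressed as a sildenafil-dose-sized 5.5 mmHg DBP decrease
the odds ratio is 1.00 with a wide CI. `leave_one_out(h)`,
`two_step_mr(h, mediator_effect(...))` and `stratified_mr(cohort, x, ld)`
run the sensitivity and stratified stages; `run_pipeline(config)` drives
everything from one YAML/list config and writes TSV + JSON results with a
run manifest.

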
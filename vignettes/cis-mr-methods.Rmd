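---
title: "Drug-target cis-MR with correlated instruments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target cis-MR with correlated instruments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The estimand and the model

Drug-target Mendelian randomisation asks what lifelong pharmacological
perturbation of a protein would do to disease risk, using cis-variants —
variants in or near the gene encoding the target — as instruments. Because
target perturbation itself is unmeasured, a downstream biomarker scales
the effect; here the template analysis is PDE5 inhibition proxied by
diastolic blood pressure (DBP, mmHg), with Alzheimer's disease (AD) as
outcome.

The core quantity is $\theta$, the log-odds of the outcome per 1 mmHg of
exposure. With per-variant exposure effects $b_{Xj}$, outcome effects
$b_{Yj}$ (log-odds) with standard errors $\sigma_{Yj}$, and the signed LD
correlation matrix $\rho$, the correlated-variant IVW estimator is the
generalised least squares solve

$$\hat\theta = (b_X^\top \Omega^{-1} b_X)^{-1} b_X^\top \Omega^{-1} b_Y,
\qquad \Omega_{jk} = \sigma_{Yj}\,\sigma_{Yk}\,\rho_{jk},$$

with $\mathrm{se}(\hat\theta) = (b_X^\top \Omega^{-1} b_X)^{-1/2}$, a Wald
95% CI and a two-sided normal p-value. Cis-instruments are deliberately
allowed to be correlated (a single locus rarely offers many independent
signals); the LD matrix carries that correlation into the weights.

Assumptions inherited from the instrumental-variable framework: the
variants associate with the exposure, affect the outcome only through it
(violations are probed by the two-step adjustment below), and share no
confounder with the outcome. Assumptions specific to this implementation:

* **First-order, fixed-effect weights.** $\Omega$ uses outcome standard
  errors only. Uncertainty in $b_X$ is ignored (no NOME correction), which
  is the standard form of the cited estimator. With weak instruments this
  dilutes $\hat\theta$ toward zero and can make coverage slightly
  anti-conservative; the per-variant F-statistic (`f_statistic()`,
  $(\beta/\mathrm{se})^2$ by default, the Cragg–Donald
  variance-explained form behind a flag) is the diagnostic.
* **Normal, not t, inference** — conventional for summary-data MR.
* **Fixed-effect model**; Cochran's Q is reported for information but no
  multiplicative inflation is applied (five instruments give Q little
  power anyway).

Estimates are re-expressed as an odds ratio per $s$ mmHg *decrease* of
exposure, $\mathrm{OR} = \exp(-s\hat\theta)$, the CI bounds swapping under
the sign change. The default $s = 5.5$ is the reported DBP reduction of a
daily 100 mg sildenafil dose; $s = 5.0$, an alternative figure quoted for
the same dose, is available by argument. Scaling is deliberately
non-idempotent: re-scaling a scaled
estimate errors rather than silently compounding.

## Instrument selection

`filter_cis()` keeps variants inside the locus (inclusive bounds, optional
flank), `filter_significance()` applies a strict `p < 5e-8` cut, and
`clump()` thins by greedy p-value priority: the lowest-p variant indexes a
window of ±10,000 kb and removes candidates with $r^2 \ge 0.35$ to it,
repeating on the remainder. Two readings were fixed once: removal happens
*at* equality ($r^2 \ge$ threshold), the conservative reading of
"survivors have $r^2 <$ threshold"; and p-value ties break by lower
position then lexicographic rsid, so the output is invariant to row order.
A naive re-implementation of the same procedure serves as the test oracle
on random instances.

## Harmonisation

Every source (exposure, outcome, optional mediator) and the LD matrix must
refer to one effect allele per variant. The anchor is the LD matrix's
recorded reference allele where known — the matrix's sign convention is
the hardest to re-derive, so everything else moves to it — and the
exposure's effect allele otherwise. Flipping a source negates its beta and
complements its allele frequency; when a variant's anchor switches
relative to the matrix convention, the matrix row and column signs flip
with it. Complementary-strand relabelling is attempted (and logged) before
declaring an allele mismatch.

Palindromic variants (A/T, C/G) cannot be oriented by labels across
strands. The default policy orients them by allele-frequency concordance
and only when the minor-allele frequency is below 0.42 on both sides;
otherwise they are excluded as ambiguous. A `drop`-all policy exists. None
of the five canonical instruments is palindromic, so the policy cannot
touch the headline analysis — which is why a frequency-based default was
considered safe. For palindromic variants the exposure's reported
orientation is taken at face value relative to the LD anchor (both come
from European reference panels); only cross-source orientation uses
frequency. Variants missing from a mandatory source are excluded with
reason `"missing"`, never silently dropped, and kept + excluded always
equals the input count.

The decisive property, enforced by test: the downstream estimate is
invariant, to machine precision, to the allele convention any input
happened to be reported on.

## Sensitivity analyses

**Leave-one-out** re-estimates $\theta$ dropping each instrument in turn
(LD restricted accordingly) — the check that no single variant drives the
result. Under an exact summary-level null each re-estimate's CI covers
zero at its nominal 95%; note that the *joint* event "all five CIs cover"
runs lower (about 86% with the synthetic LD used here) because the
re-estimates are correlated but not perfectly so.

**Two-step cis-MR** guards against a known pleiotropy route: instruments
may act on the outcome through a correlated trait (body-mass index is the
template — its presence as a covariate in the exposure GWAS can induce
collider structure). Given an external mediator-on-outcome effect
$\beta_{CO}$ (se $\sigma_{CO}$) and harmonised variant-mediator effects
$b_{Cj}$:

$$b_{Yj}^{adj} = b_{Yj} - b_{Cj}\beta_{CO}, \qquad
\sigma_{Yj}^{adj} = \sqrt{\sigma_{Yj}^2 + b_{Cj}^2\sigma_{CO}^2 +
\beta_{CO}^2\sigma_{Cj}^2},$$

first-order propagation with independence across terms (the two-sample
setting), so the adjusted SE never shrinks. $\beta_{CO}$ is a supplied
input, not estimated internally — estimating it would be its own MR
analysis. On a simulated pure variant→mediator→outcome path the
unadjusted estimate is biased and the adjustment removes the bias; that is
asserted in the test suite at Monte-Carlo tolerance.

**Uncorrelated IVW** (`mr_ivw_uncorrelated()`) is the closed-form
$\rho = I$ special case, used for the protein-level (pQTL) instruments,
and doubles as a cross-check: the correlated path must reproduce it
exactly on identity LD.

## The sex-stratified individual-level stage

AD is more prevalent in women while sildenafil is prescribed almost
exclusively to men, so the pipeline re-estimates per sex. The cohort is
first restricted to AD cases versus dementia-free controls
(`apply_exclusions()` removes vascular, frontotemporal and other-dementia
labels, with counts logged). Per variant and sex, `fit_variant_outcome()`
fits maximum-likelihood logistic regression of case status on dosage plus
age, genotyping batch (indicator-coded, first level reference) and ten
genetic principal components; the dosage coefficient is the log-odds
per-allele association. The same sex-combined exposure effects are paired
with both sexes' outcome fits (variant-exposure effects are taken as
sex-identical), and the correlated IVW and dose scaling run per sex.

Numerical choices: IRLS with a 1e-12 deviance tolerance and 100-iteration
cap; non-convergence errors with diagnostics; complete or quasi-complete
separation (fitted probabilities numerically 0 or 1) is flagged as an
error rather than returned as a huge coefficient — with ~0.8% case
fractions that failure mode is real. Plain ML is the biobank convention;
a Firth-type bias-reduced fit (hat-value-adjusted score,
implemented in the package) is available by flag for rare-event
simulation work. Dosages may be fractional; nothing is hard-called.

## The synthetic-data generator

The generator exists so that every stage — including LD-aware estimation —
can be exercised end to end without any external download. It emulates:

* **Genotypes with controllable LD.** Two haplotypes per person are drawn
  from a Gaussian copula: correlated standard normals thresholded at
  `qnorm(maf)`. The latent correlation per pair is solved numerically
  (root finding on the thresholded-variable correlation, with the
  bivariate-normal orthant probability computed by 1-D quadrature over
  the conditional CDF) so the *dosage* correlation hits the target LD;
  infeasible targets — beyond the Fréchet-type bound at the given
  frequencies — error with the attainable range. A multinomial per-SNP
  draw could not hit a target LD matrix, which is why the copula route
  was chosen.
* **Marginal effect semantics.** Configured per-variant exposure (and
  mediator) effects are *marginal* per-allele effects — what a GWAS
  reports and what instrument tables print. Internally the generator
  solves for joint generative effects via the LD-implied dosage
  covariance (Hardy–Weinberg variances) so the simulated summary
  statistics reproduce the configured effects. The defaults are the five
  canonical instruments' frequencies and mmHg effects, residual exposure
  SD 10 mmHg (so each variant explains roughly 0.01% of variance, the
  realistic weak-instrument regime), and a synthetic five-variant LD
  matrix whose pairwise correlations were chosen once to be plausible for
  a clumped cis set (all $r^2 < 0.35$, mixed signs, positive definite,
  copula-attainable).
* **A rare binary outcome.** Case labels come from a logistic model whose
  intercept is solved numerically so the marginal case fraction equals
  the target (default 0.8%, the case–control imbalance of the
  sex-stratified biobank cohorts). A logistic rather than
  liability-threshold model matches the logistic estimation stage, so
  parameter recovery is clean up to noncollapsibility, which matters only
  when a high-variance mediator enters the linear predictor.
* **Two-sample structure.** Exposure and outcome (and mediator) summary
  statistics come from disjoint splits of one genotype pool — no person
  contributes to two sources, mirroring the overlap-avoidance rationale
  of two-sample MR.
* **A biobank-like cohort** with balanced sex, age ~ N(57, 8), three
  genotyping batches, ten standard-normal PCs, an age effect on risk
  (log-OR 0.1/year by default), and other-dementia labels at ~1.2% in
  total (0.7% vascular, 0.2% frontotemporal, 0.3% other), roughly the
  fraction the exclusion stage removes in comparable biobank cohorts.

What the generator does **not** emulate: population structure beyond
noise PCs, genotyping/imputation error, age- and sex-dependent allele
effects, survival bias, and the case ascertainment quirks of real
biobanks. Passing tests therefore demonstrate estimator correctness and
calibration under the assumed causal model, not robustness to those
real-data features.

All generator entry points are deterministic given the config (seed
included); replicate loops can pass a precomputed `latent_correlation()`
to skip the per-pair root finding.

## Problem sizes and numerical choices in the test suite

The suite's simulation studies use two-sample cohorts of 20,000 with a
0.8% outcome rate (500 replicates per causal-effect value across
$\theta^* \in \{0, \pm 0.01, \pm 0.02\}$), 200 replicates for the
two-step bias-removal study, and 100 replicates of a 20,000-person cohort
for the stratified null-calibration study — sizes chosen so the whole
suite runs on a laptop core while keeping Monte-Carlo error well inside
the asserted tolerances. Estimator-vs-oracle agreement is asserted at
1e-10 against an explicit-inverse GLS solve, identity-LD equivalence at
1e-12, and the closed-form logistic toy at 1e-8.

Remaining numerical guards: a near-singular user-supplied LD matrix
(condition number above 1e8) receives a reported ridge `rho + 1e-6 I`
before the Cholesky solve — instruments surviving `r^2 < 0.35` clumping
never trigger it; LD files are symmetrised as $(M + M^\top)/2$ when the
asymmetry is small and rejected otherwise; eigenvalue flooring keeps the
assembled latent copula matrix positive semidefinite.

## Known limitations

* Exposure-side uncertainty is ignored in the weights (no NOME
  correction); at the reduced simulated sample sizes this shows up as
  mild dilution of recovered effects, and it is why instrument strength
  is reported.
* No MR-Egger, weighted-median/mode, multivariable MR or colocalisation —
  deliberately out of scope; the single-locus, correlated-instrument
  design does not support the first two, and the others are separate
  analyses.
* The shipped LD matrix and outcome associations are synthetic stand-ins;
  headline numbers from real analyses are reproducible only with the
  original reference panels and GWAS, which are not redistributed here.
* Genome-build liftover is not implemented; coordinates are GRCh37
  throughout.
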
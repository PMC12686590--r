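# Regenerates the plain-text fixtures under inst/extdata/.
# Run from the package root after installing the package.
library(cismr)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

t1 <- table1_fixture()
write_summary_stats(t1, "inst/extdata/pde5_dbp_instruments.tsv")

ld <- synthetic_ld_fixture()
write_ld_matrix(ld, "inst/extdata/synthetic_pde5_ld.tsv")

# Synthetic stand-in for per-variant AD associations at the scale of the
# main outcome GWAS (54,162 participants, 17,008 cases), generated under a
# null causal effect. A stand-in only: no real variant-outcome effects are
# shipped here.
cfg <- sim_config(n_exposure_cohort = 2L, n_outcome_cohort = 54162L,
                  base_case_rate = 17008 / 54162, theta_star = 0,
                  seed = 70265L)
sim <- simulate_two_sample(cfg)
write_summary_stats(sim$outcome, "inst/extdata/synthetic_ad_outcome.tsv")
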
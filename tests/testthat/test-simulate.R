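test_that("independent genotypes are uncorrelated with the right frequencies", {
  g <- simulate_genotypes(10000, mafs = c(0.48, 0.2, 0.05), seed = 1)
  expect_true(all(g %in% 0:2))
  r <- cor(g)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  expect_lt(abs(mean(g[, 1]) - 0.96), 0.03)
  expect_lt(abs(mean(g[, 2]) - 0.4), 0.03)
})

test_that("copula genotypes hit a target LD correlation", {
  rho <- matrix(c(1, 0.5, 0.5, 1), 2)
  ld <- ld_matrix(rho, rsids = c("a", "b"))
  g <- simulate_genotypes(10000, mafs = c(0.3, 0.4), ld_target = ld,
                          seed = 2)
  expect_equal(cor(g)[1, 2], 0.5, tolerance = 0.05)
  # signed LD carries through too
  rho_neg <- matrix(c(1, -0.4, -0.4, 1), 2)
  g2 <- simulate_genotypes(10000, mafs = c(0.3, 0.4),
                           ld_target = ld_matrix(rho_neg,
                                                 rsids = c("a", "b")),
                           seed = 3)
  expect_equal(cor(g2)[1, 2], -0.4, tolerance = 0.05)
})

test_that("infeasible LD targets are rejected with the attainable range", {
  rho <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_error(latent_correlation(rho, mafs = c(0.48, 0.03)),
               "infeasible")
})

test_that("phenotype generator hits the target case rate and null model", {
  cfg <- sim_config(theta_star = 0, base_case_rate = 0.008, seed = 4)
  cfg$latent <- latent_correlation(cfg$ld_target, cfg$mafs)
  set.seed(4)
  g <- simulate_genotypes(50000, cfg$mafs, cfg$ld_target,
                          latent = cfg$latent)
  ph <- simulate_phenotypes(g, cfg)
  expect_lt(abs(mean(ph$case) - 0.008), 0.002)
  expect_null(ph$mediator)
  # null model: per-variant association z-scores behave like noise
  stats <- summarize_cohort(g, ph$case, "binary")
  expect_true(all(abs(stats$beta / stats$se) < 4))
})

test_that("a protective causal effect lowers case odds with exposure", {
  cfg <- sim_config(theta_star = -0.05, base_case_rate = 0.05, seed = 5,
                    n_exposure_cohort = 50000)
  cfg$latent <- latent_correlation(cfg$ld_target, cfg$mafs)
  set.seed(5)
  g <- simulate_genotypes(50000, cfg$mafs, cfg$ld_target,
                          latent = cfg$latent)
  ph <- simulate_phenotypes(g, cfg)
  expect_lt(mean(ph$exposure[ph$case == 1]), mean(ph$exposure[ph$case == 0]))
})

test_that("cohort summaries reproduce the configured marginal effects at zero noise", {
  # independent variants: marginal and joint effects coincide
  betas <- c(0.25, 0, 0, 0, 0)
  cfg <- sim_config(snp_exposure_betas = betas, exposure_sd = 1e-6,
                    ld_target = diag(5), mafs = table1_fixture()$eaf,
                    seed = 6)
  set.seed(6)
  g <- simulate_genotypes(5000, cfg$mafs, cfg$ld_target)
  ph <- simulate_phenotypes(g, cfg)
  stats <- summarize_cohort(g, ph$exposure, "continuous")
  expect_equal(stats$beta[1], 0.25, tolerance = 1e-3)
  expect_equal(stats$eaf, unname(colMeans(g) / 2), tolerance = 1e-12)
  # under LD, the per-variant summary betas converge to the configured
  # marginal effects, not the internal joint ones
  cfg2 <- sim_config(exposure_sd = 1e-6, seed = 66)
  cfg2$latent <- latent_correlation(cfg2$ld_target, cfg2$mafs)
  set.seed(66)
  g2 <- simulate_genotypes(50000, cfg2$mafs, cfg2$ld_target,
                           latent = cfg2$latent)
  ph2 <- simulate_phenotypes(g2, cfg2)
  stats2 <- summarize_cohort(g2, ph2$exposure, "continuous")
  expect_true(all(abs(stats2$beta - table1_fixture()$beta) < 0.015))
})

test_that("summary p-values are uniform under a permuted phenotype", {
  set.seed(8)
  m <- 60
  g <- simulate_genotypes(2000, mafs = rep(0.3, m))
  y <- rnorm(2000)
  info <- make_assoc(sprintf("s%02d", 1:m), NA, NA, pos = 1:m)
  info$beta <- 0; info$se <- 1
  stats <- summarize_cohort(g, sample(y), "continuous", variant_info = info)
  ks <- suppressWarnings(ks.test(stats$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical EAFs track the configured frequencies", {
  t1 <- table1_fixture()
  g <- simulate_genotypes(10000, t1$eaf, synthetic_ld_fixture(), seed = 9)
  expect_true(all(abs(unname(colMeans(g) / 2) - t1$eaf) < 0.02))
})

test_that("two-sample generator is deterministic and uses disjoint cohorts", {
  cfg <- sim_config(n_exposure_cohort = 1500, n_outcome_cohort = 1500,
                    seed = 10)
  cfg$latent <- latent_correlation(cfg$ld_target, cfg$mafs)
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcome, b$outcome)
  # exposure and outcome summaries come from different people
  expect_false(isTRUE(all.equal(a$exposure$eaf, a$outcome$eaf)))
  cfg2 <- cfg; cfg2$seed <- 11L
  c2 <- simulate_two_sample(cfg2)
  expect_false(identical(a$exposure$beta, c2$exposure$beta))
})

test_that("the canonical instrument fixture matches the published table", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 5L)
  expect_equal(t1$rsid[1], "rs66887589")
  expect_equal(t1$beta, c(0.16, -0.13, -0.10, 0.10, -0.14))
  expect_equal(t1$se, c(0.02, 0.02, 0.02, 0.03, 0.05))
  expect_equal(t1$eaf, c(0.48, 0.34, 0.22, 0.14, 0.03))
  expect_equal(t1$effect_allele, c("C", "C", "T", "A", "C"))
  expect_true(all(t1$se > 0))
  ld <- synthetic_ld_fixture()
  expect_equal(ld$rsids, t1$rsid)
  expect_true(all(ld$rho[upper.tri(ld$rho)]^2 < 0.35))
  expect_gt(min(eigen(ld$rho, only.values = TRUE)$values), 0)
})

test_that("simulated cohorts carry covariates, labels and dosage columns", {
  cfg <- sim_config(seed = 12, n_individual_cohort = 4000)
  cfg$latent <- latent_correlation(cfg$ld_target, cfg$mafs)
  cohort <- simulate_cohort(cfg)
  expect_setequal(setdiff(unique(cohort$dementia_label), ""),
                  intersect(unique(cohort$dementia_label),
                            c("none", "AD", "vascular", "frontotemporal",
                              "other")))
  expect_true(all(paste0("dosage_", table1_fixture()$rsid) %in%
                    names(cohort)))
  expect_true(all(paste0("pc", 1:10) %in% names(cohort)))
  expect_setequal(unique(cohort$sex), c("female", "male"))
  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort, cohort2)
})
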
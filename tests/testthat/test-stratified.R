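make_toy_cohort <- function(n_case_by_dosage, n_ctrl_by_dosage) {
  # counts indexed by dosage value 0/1
  dosage <- c(rep(0, n_case_by_dosage[1]), rep(1, n_case_by_dosage[2]),
              rep(0, n_ctrl_by_dosage[1]), rep(1, n_ctrl_by_dosage[2]))
  label <- c(rep("AD", sum(n_case_by_dosage)),
             rep("none", sum(n_ctrl_by_dosage)))
  data.frame(id = seq_along(dosage), sex = "female",
             dosage_rsX = dosage, dementia_label = label,
             stringsAsFactors = FALSE)
}

test_that("exclusions remove exactly the other-dementia labels", {
  set.seed(42)
  n <- 1000
  label <- rep("none", n)
  label[1:10] <- "vascular"
  label[11:15] <- "frontotemporal"
  label[16:18] <- "other"
  label[19:30] <- "AD"
  cohort <- data.frame(id = 1:n, dementia_label = sample(label))
  out <- suppressMessages(apply_exclusions(cohort))
  expect_equal(nrow(out), 982L)
  expect_setequal(unique(out$dementia_label), c("none", "AD"))
  all_none <- data.frame(id = 1:5, dementia_label = "none")
  expect_equal(apply_exclusions(all_none), all_none)
  expect_error(apply_exclusions(data.frame(dementia_label = "AD?")),
               "unknown")
})

test_that("covariate-free logistic fit equals the 2x2 contingency log-OR", {
  # dosage 1: 10 cases / 90 controls; dosage 0: 20 cases / 80 controls
  cohort <- make_toy_cohort(n_case_by_dosage = c(20, 10),
                            n_ctrl_by_dosage = c(80, 90))
  fit <- fit_variant_outcome(cohort, "rsX")
  expect_equal(fit$beta, log((10 * 80) / (90 * 20)), tolerance = 1e-8)
  expect_equal(fit$beta, log(800 / 1800), tolerance = 1e-8)
  expect_equal(fit$n, 200L)
  # balanced counts give a null coefficient
  null_fit <- fit_variant_outcome(
    make_toy_cohort(c(10, 10), c(90, 90)), "rsX")
  expect_equal(null_fit$beta, 0, tolerance = 1e-8)
})

test_that("degenerate and single-sex inputs raise informative errors", {
  cohort <- make_toy_cohort(c(10, 10), c(90, 90))
  cohort$dosage_rsX <- 1
  expect_error(fit_variant_outcome(cohort, "rsX"), "constant")
  cohort2 <- make_toy_cohort(c(10, 10), c(90, 90))
  expect_error(fit_variant_outcome(cohort2, "rsX", sex = "male"), "male")
  expect_error(fit_variant_outcome(cohort2, "rsY"), "rsY")
  with_vasc <- make_toy_cohort(c(10, 10), c(90, 90))
  with_vasc$dementia_label[1] <- "vascular"
  expect_error(fit_variant_outcome(with_vasc, "rsX"), "apply_exclusions")
})

test_that("dosage coefficient is null-calibrated under no association", {
  set.seed(314)
  n <- 5000
  ok <- 0L
  for (r in 1:100) {
    dosage <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.05)
    cohort <- data.frame(id = 1:n, sex = "female", dosage_rsN = dosage,
                         dementia_label = ifelse(y == 1, "AD", "none"))
    fit <- fit_variant_outcome(cohort, "rsN")
    ok <- ok + (abs(fit$beta) < 3 * fit$se)
  }
  expect_gte(ok, 99L)
})

test_that("firth-type bias reduction matches ML closely away from sparsity", {
  set.seed(99)
  n <- 4000
  dosage <- rbinom(n, 2, 0.4)
  age <- rnorm(n, 57, 8)
  lp <- -2 + 0.3 * dosage + 0.02 * (age - 57)
  y <- rbinom(n, 1, plogis(lp))
  cohort <- data.frame(id = 1:n, sex = "male", dosage_rs1 = dosage,
                       age = age,
                       dementia_label = ifelse(y == 1, "AD", "none"))
  ml <- fit_variant_outcome(cohort, "rs1")
  br <- fit_variant_outcome(cohort, "rs1", bias_reduction = TRUE)
  expect_equal(br$beta, ml$beta, tolerance = 0.02)
  expect_equal(br$se, ml$se, tolerance = 0.02)
})

test_that("stratified pipeline runs per sex and reports case fractions", {
  t1 <- table1_fixture()
  ld <- synthetic_ld_fixture()
  cfg <- sim_config(seed = 321, n_individual_cohort = 12000,
                    base_case_rate = 0.01)
  cfg$latent <- latent_correlation(ld, cfg$mafs)
  cohort <- suppressMessages(apply_exclusions(simulate_cohort(cfg)))
  res <- suppressMessages(stratified_mr(cohort, t1, ld))
  expect_s3_class(res$female, "mr_estimate")
  expect_s3_class(res$male, "mr_estimate")
  expect_equal(res$female$scale_mmhg, 5.5)
  expect_true(all(res$case_fraction > 0 & res$case_fraction < 0.05))
  # a males-only cohort cannot support the female analysis
  males <- cohort[cohort$sex == "male", ]
  expect_error(suppressMessages(stratified_mr(males, t1, ld)),
               "no female")
})
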
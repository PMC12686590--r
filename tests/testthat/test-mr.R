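test_that("single-SNP IVW reduces to the ratio estimate", {
  h <- harmonised_set(bx = 0.1, sx = 0.02, by = 0.05, sy = 0.01)
  e <- mr_ivw_correlated(h)
  expect_equal(e$theta, 0.5, tolerance = 1e-12)
  expect_equal(e$se_theta, 0.1, tolerance = 1e-12)
  expect_equal(e$ci_low, 0.5 - 1.959964 * 0.1, tolerance = 1e-12)
})

test_that("null outcome vector gives theta 0 and scaled OR 1", {
  h <- harmonised_set(bx = c(0.1, 0.2), sx = 0.02, by = c(0, 0),
                      sy = c(0.01, 0.02))
  e <- scale_estimate(mr_ivw_correlated(h), 5.5)
  expect_equal(e$theta, 0)
  expect_equal(e$scaled_or, 1.0)
})

test_that("3-SNP correlated IVW matches the brute-force GLS oracle", {
  bx <- c(0.1, 0.2, 0.15)
  by <- c(0.02, 0.05, 0.03)
  sy <- c(0.01, 0.02, 0.015)
  rho <- matrix(c(1, 0.3, 0.1,
                  0.3, 1, 0.2,
                  0.1, 0.2, 1), 3, 3)
  h <- harmonised_set(bx, sx = 0.02, by, sy, rho = rho)
  e <- mr_ivw_correlated(h)
  o <- gls_oracle(bx, by, sy, rho)
  expect_equal(e$theta, o$theta, tolerance = 1e-12)
  expect_equal(e$se_theta, o$se, tolerance = 1e-12)
})

test_that("correlated IVW equals the closed-form when LD is the identity", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(1:6, 1)
    h <- harmonised_set(bx = rnorm(m, 0.15, 0.05), sx = 0.02,
                        by = rnorm(m, 0, 0.05),
                        sy = runif(m, 0.01, 0.08))
    a <- mr_ivw_correlated(h)
    b <- mr_ivw_uncorrelated(h)
    expect_equal(a$theta, b$theta, tolerance = 1e-12)
    expect_equal(a$se_theta, b$se_theta, tolerance = 1e-12)
  }
})

test_that("uncorrelated IVW closed-form behaviour on duplicated instruments", {
  one <- mr_ivw_uncorrelated(harmonised_set(0.1, 0.02, 0.05, 0.01))
  two <- mr_ivw_uncorrelated(harmonised_set(c(0.1, 0.1), 0.02,
                                            c(0.05, 0.05), c(0.01, 0.01)))
  expect_equal(two$theta, one$theta, tolerance = 1e-12)
  expect_equal(two$se_theta, one$se_theta / sqrt(2), tolerance = 1e-12)
})

test_that("dose scaling maps theta to OR per mmHg decrease, once only", {
  h <- harmonised_set(0.1, 0.02, 0.002, 0.01)
  e <- mr_ivw_correlated(h)
  e$theta <- 0.02
  e$ci_low <- 0.01
  e$ci_high <- 0.03
  s <- scale_estimate(e, 5.5)
  expect_equal(s$scaled_or, exp(-0.11), tolerance = 1e-12)
  expect_equal(s$scaled_ci_low, exp(-5.5 * 0.03), tolerance = 1e-12)
  expect_equal(s$scaled_ci_high, exp(-5.5 * 0.01), tolerance = 1e-12)
  expect_true(s$scaled_ci_low <= s$scaled_or &&
                s$scaled_or <= s$scaled_ci_high)
  expect_error(scale_estimate(s, 5.5), "twice")
  expect_error(scale_estimate(e, -1), "positive")
})

test_that("standard errors scale linearly in the outcome SEs", {
  set.seed(11)
  m <- 5
  rho <- random_corr(m)
  h <- harmonised_set(bx = rnorm(m, 0.15, 0.04), sx = 0.02,
                      by = rnorm(m, 0, 0.04), sy = runif(m, 0.01, 0.05),
                      rho = rho)
  e1 <- mr_ivw_correlated(h)
  h$sy <- 3 * h$sy
  e3 <- mr_ivw_correlated(h)
  expect_equal(e3$se_theta, 3 * e1$se_theta, tolerance = 1e-12)
})

test_that("near-singular LD triggers reported ridge conditioning", {
  rho <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2)
  h <- harmonised_set(bx = c(0.1, 0.12), sx = 0.02, by = c(0.02, 0.03),
                      sy = c(0.01, 0.015), rho = rho)
  e <- mr_ivw_correlated(h)
  expect_gt(e$ridge_applied, 0)
  expect_true(is.finite(e$theta))
  expect_error(mr_ivw_correlated(h, ridge = 0), "singular")
})

test_that("leave-one-out returns one estimate per omitted instrument", {
  t1 <- table1_fixture()
  out <- t1
  out$beta <- c(0.01, -0.02, 0.00, 0.02, -0.01)
  out$se <- rep(0.04, 5)
  h <- harmonise(t1, out, synthetic_ld_fixture())
  loo <- leave_one_out(h)
  expect_named(loo, t1$rsid)
  expect_equal(length(loo), 5L)
  expect_equal(loo[[1]]$n_snps, 4L)
  # two duplicated instruments: every re-estimate is the single-SNP ratio
  h2 <- harmonised_set(c(0.1, 0.1), 0.02, c(0.05, 0.05), c(0.01, 0.01),
                       rho = matrix(c(1, 0.3, 0.3, 1), 2))
  loo2 <- leave_one_out(h2)
  expect_equal(loo2[[1]]$theta, 0.5, tolerance = 1e-12)
  expect_equal(loo2[[2]]$theta, 0.5, tolerance = 1e-12)
  expect_error(leave_one_out(harmonised_set(0.1, 0.02, 0.05, 0.01)),
               "at least 2")
})

test_that("leave-one-out CIs cover the null in a summary-level simulation", {
  set.seed(909)
  t1 <- table1_fixture()
  ld <- synthetic_ld_fixture()
  sy <- rep(0.04, 5)
  omega_ch <- chol(outer(sy, sy) * ld$rho)
  n_rep <- 200L
  cover <- matrix(NA, n_rep, 5)
  for (r in seq_len(n_rep)) {
    by <- drop(rnorm(5) %*% omega_ch)            # null outcome effects
    h <- harmonised_set(t1$beta, t1$se, by, sy, rho = ld$rho,
                        rsids = t1$rsid)
    loo <- leave_one_out(h)
    cover[r, ] <- vapply(loo, function(e) e$ci_low <= 0 && e$ci_high >= 0,
                         logical(1))
  }
  # each re-estimate's 95% CI is calibrated under the null
  expect_true(all(colMeans(cover) >= 0.90))
  # and in most replicates the whole leave-one-out panel covers zero
  expect_gte(mean(rowMeans(cover) == 1), 0.80)
})
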
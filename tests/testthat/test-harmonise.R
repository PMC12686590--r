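test_that("flip swaps alleles, negates beta, complements EAF; involution", {
  x <- make_assoc("rs66887589", 0.16, 0.02, eaf = 0.48, ea = "C", oa = "T")
  f <- flip_variant(x)
  expect_equal(f$effect_allele, "T")
  expect_equal(f$other_allele, "C")
  expect_equal(f$beta, -0.16)
  expect_equal(f$eaf, 0.52)
  expect_equal(f$se, x$se)
  expect_equal(f$pvalue, x$pvalue)
  expect_equal(flip_variant(f), x)
  z <- make_assoc("rs0", 0, 0.02)
  expect_equal(flip_variant(z)$beta, 0)
})

aligned_inputs <- function() {
  exposure <- make_assoc(c("rs1", "rs2"), c(0.1, -0.2), 0.02,
                         eaf = c(0.3, 0.4), ea = c("A", "C"),
                         oa = c("G", "T"))
  outcome <- make_assoc(c("rs1", "rs2"), c(0.02, -0.01), 0.05,
                        eaf = c(0.3, 0.4), ea = c("A", "C"),
                        oa = c("G", "T"))
  rho <- matrix(c(1, 0.4, 0.4, 1), 2)
  ld <- ld_matrix(rho, rsids = c("rs1", "rs2"),
                  ref_alleles = c("A", "C"))
  list(exposure = exposure, outcome = outcome, ld = ld)
}

test_that("already-aligned sources pass through with no flips", {
  inp <- aligned_inputs()
  h <- harmonise(inp$exposure, inp$outcome, inp$ld)
  expect_equal(h$bx, inp$exposure$beta)
  expect_equal(h$by, inp$outcome$beta)
  expect_equal(nrow(h$flips), 0L)
  expect_equal(nrow(h$exclusions), 0L)
})

test_that("outcome on the opposite allele is flipped and logged", {
  inp <- aligned_inputs()
  inp$outcome[1, ] <- flip_variant(inp$outcome[1, ])
  h <- harmonise(inp$exposure, inp$outcome, inp$ld)
  expect_equal(h$by, c(0.02, -0.01))
  expect_equal(h$flips$source, "outcome")
  expect_equal(h$flips$rsid, "rs1")
})

test_that("missing and mismatched variants are excluded with reasons", {
  inp <- aligned_inputs()
  h <- harmonise(inp$exposure, inp$outcome[2, ], inp$ld)
  expect_equal(h$rsids, "rs2")
  expect_equal(h$exclusions$reason, "missing")
  # mismatched allele pair
  inp2 <- aligned_inputs()
  inp2$outcome$effect_allele[1] <- "C"
  inp2$outcome$other_allele[1] <- "G"
  h2 <- harmonise(inp2$exposure, inp2$outcome, inp2$ld)
  expect_equal(h2$exclusions$reason, "allele_mismatch")
  # kept + excluded = input
  expect_equal(length(h2$rsids) + nrow(h2$exclusions), nrow(inp2$exposure))
})

test_that("palindromic variants resolve by EAF concordance or drop out", {
  pal_x <- make_assoc("rsP", 0.1, 0.02, eaf = 0.10, ea = "A", oa = "T")
  ld <- ld_matrix(diag(1), rsids = "rsP", ref_alleles = "A")
  # concordant minor allele, reported on the other strand's labels
  pal_y <- make_assoc("rsP", -0.05, 0.04, eaf = 0.88, ea = "A", oa = "T")
  h <- harmonise(pal_x, pal_y, ld)
  expect_equal(h$by, 0.05)           # discordant EAF => strand flip applied
  # ambiguous frequency near 0.5 is excluded under the default policy
  pal_y2 <- make_assoc("rsP", -0.05, 0.04, eaf = 0.50, ea = "A", oa = "T")
  expect_error(harmonise(pal_x, pal_y2, ld), "no variants survive")
  two <- rbind(pal_x, make_assoc("rsQ", 0.2, 0.02, eaf = 0.3,
                                 ea = "C", oa = "T", pos = 2))
  two_y <- rbind(pal_y2, make_assoc("rsQ", 0.1, 0.04, eaf = 0.3,
                                    ea = "C", oa = "T", pos = 2))
  ld2 <- ld_matrix(diag(2), rsids = c("rsP", "rsQ"),
                   ref_alleles = c("A", "C"))
  h2 <- harmonise(two, two_y, ld2)
  expect_equal(h2$exclusions$reason, "palindromic_ambiguous")
  expect_equal(h2$rsids, "rsQ")
  # drop-all policy removes palindromic variants outright
  h3 <- harmonise(two, two_y, ld2, palindromic = "drop")
  expect_equal(h3$rsids, "rsQ")
})

test_that("strand-complement relabelling rescues non-palindromic variants", {
  inp <- aligned_inputs()
  # outcome rs1 reported as T/C (complement of A/G)
  inp$outcome$effect_allele[1] <- "T"
  inp$outcome$other_allele[1] <- "C"
  h <- harmonise(inp$exposure, inp$outcome, inp$ld)
  expect_equal(h$by, c(0.02, -0.01))
  expect_true("strand_relabel" %in% h$flips$action)
  # with strand flips disabled the variant is a mismatch
  h2 <- harmonise(inp$exposure, inp$outcome, inp$ld, strand_flip = FALSE)
  expect_equal(h2$exclusions$reason, "allele_mismatch")
})

test_that("downstream IVW is invariant to input allele conventions", {
  set.seed(33)
  m <- 5
  t1 <- table1_fixture()
  ld <- synthetic_ld_fixture()
  outcome <- t1
  outcome$beta <- rnorm(m, 0, 0.05)
  outcome$se <- rep(0.04, m)
  base <- mr_ivw_correlated(harmonise(t1, outcome, ld))
  for (i in 1:25) {
    fx <- runif(m) < 0.5
    fy <- runif(m) < 0.5
    h <- harmonise(random_flip(t1, fx), random_flip(outcome, fy), ld)
    e <- mr_ivw_correlated(h)
    expect_equal(e$theta, base$theta, tolerance = 1e-12)
    expect_equal(e$se_theta, base$se_theta, tolerance = 1e-12)
  }
})
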
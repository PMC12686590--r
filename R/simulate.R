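#' The five DBP instruments at the PDE5A locus
#'
#' Returns the five cis-instruments used to proxy PDE5 inhibition, with
#' their diastolic-blood-pressure effects (mmHg per effect allele),
#' standard errors, effect-allele frequencies, DBP and eQTL p-values and
#' sample sizes. Positions are synthetic placeholders spaced within the
#' PDE5A locus (chr4:120,415,550-120,550,146, GRCh37); per-variant
#' positions are not part of the canonical instrument table and only the
#' locus bounds are meaningful.
#'
#' @return variant-association table of five rows (exposure scale, extra
#'   column `eqtl_pvalue`).
#' @export
table1_fixture <- function() {
  x <- data.frame(
    rsid = c("rs66887589", "rs10050092", "rs12646525", "rs80223330",
             "rs17355550"),
    chrom = "4",
    pos = c(120431000L, 120445000L, 120470000L, 120500000L, 120535000L),
    effect_allele = c("C", "C", "T", "A", "C"),
    other_allele = c("T", "T", "C", "G", "T"),
    eaf = c(0.48, 0.34, 0.22, 0.14, 0.03),
    beta = c(0.16, -0.13, -0.10, 0.10, -0.14),
    se = c(0.02, 0.02, 0.02, 0.03, 0.05),
    pvalue = c(2e-20, 9e-13, 7e-06, 1e-04, 4e-03),
    n = c(754581L, 754583L, 746319L, 749960L, 746320L),
    stringsAsFactors = FALSE
  )
  x$eqtl_pvalue <- c(1.9e-40, 1.5e-18, 1.5e-9, 2.1e-34, 3.5e-8)
  validate_assoc(x)
  x
}

#' Synthetic LD matrix for the five PDE5A instruments
#'
#' A synthetic stand-in for the European-ancestry LD correlation matrix
#' over the five instruments (no real reference-panel matrix for these
#' variants is redistributed here). Pairwise signed correlations
#' were chosen once to be plausible for a clumped cis-instrument set: all
#' r-squared below 0.35, mixed signs, positive definite, and attainable by
#' the Gaussian-copula genotype generator at the instruments' allele
#' frequencies.
#'
#' @return an [ld_matrix()] anchored on the instruments' effect alleles.
#' @export
synthetic_ld_fixture <- function() {
  t1 <- table1_fixture()
  rho <- matrix(c(
    1.00,  0.55,  0.40, -0.20,  0.10,
    0.55,  1.00,  0.50, -0.15,  0.05,
    0.40,  0.50,  1.00, -0.10,  0.15,
   -0.20, -0.15, -0.10,  1.00,  0.30,
    0.10,  0.05,  0.15,  0.30,  1.00), 5, 5)
  ld_matrix(rho, rsids = t1$rsid, ref_alleles = t1$effect_allele)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults are the
#' reference conditions: the five instruments' allele frequencies and mmHg
#' effects, a diastolic-blood-pressure-like exposure (residual SD 10 mmHg,
#' so each variant explains roughly 0.01% of variance), a rare binary
#' outcome with a 0.8% case fraction as in the sex-stratified biobank
#' cohorts, and a null causal effect.
#'
#' @param n_exposure_cohort,n_outcome_cohort sizes of the two disjoint
#'   summary-statistic cohorts (default 20,000 each).
#' @param n_individual_cohort size of the individual-level cohort
#'   (default 20,000).
#' @param mafs per-variant effect-allele frequencies.
#' @param ld_target [ld_matrix()] (or plain correlation matrix) the
#'   genotypes should exhibit.
#' @param snp_exposure_betas per-variant marginal (GWAS-scale) exposure
#'   effects, mmHg per allele. The generator reproduces these in the
#'   simulated summary statistics: internally it solves for the joint
#'   generative effects under the target LD, since a GWAS reports
#'   single-variant regressions that tag correlated neighbours.
#' @param theta_star true causal effect, log-odds of outcome per mmHg.
#' @param exposure_sd residual SD of the exposure in mmHg (default 10).
#' @param base_case_rate marginal outcome prevalence (default 0.008).
#' @param mediator_path optional list with `bc` (per-variant marginal
#'   variant-to-mediator betas), `beta_co` (mediator-to-outcome log-odds
#'   per unit), `mediator_sd` (residual SD, default 1) and optionally
#'   `n_mediator_cohort` (default `n_exposure_cohort`) for the
#'   pleiotropy simulations.
#' @param covariate_effects named list of log-odds effects of cohort
#'   covariates on the outcome (default `list(age = 0.1)` per year,
#'   centred).
#' @param seed integer seed; every generator call is deterministic given
#'   the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_exposure_cohort = 20000,
                       n_outcome_cohort = 20000,
                       n_individual_cohort = 20000,
                       mafs = table1_fixture()$eaf,
                       ld_target = synthetic_ld_fixture(),
                       snp_exposure_betas = table1_fixture()$beta,
                       theta_star = 0,
                       exposure_sd = 10,
                       base_case_rate = 0.008,
                       mediator_path = NULL,
                       covariate_effects = list(age = 0.1),
                       seed = 20251013) {
  stopifnot(n_exposure_cohort >= 1, n_outcome_cohort >= 1,
            n_individual_cohort >= 1,
            all(mafs > 0 & mafs < 1),
            base_case_rate > 0 && base_case_rate < 1,
            length(snp_exposure_betas) == length(mafs),
            exposure_sd > 0)
  if (inherits(ld_target, "ld_matrix")) {
    stopifnot(length(ld_target$rsids) == length(mafs))
  } else {
    ld_target <- ld_matrix(ld_target,
                           rsids = paste0("snp", seq_along(mafs)))
  }
  if (!is.null(mediator_path)) {
    stopifnot(length(mediator_path$bc) == length(mafs),
              is.numeric(mediator_path$beta_co))
    if (is.null(mediator_path$mediator_sd)) mediator_path$mediator_sd <- 1
    if (is.null(mediator_path$n_mediator_cohort)) {
      mediator_path$n_mediator_cohort <- n_exposure_cohort
    }
  }
  structure(list(
    n_exposure_cohort = as.integer(n_exposure_cohort),
    n_outcome_cohort = as.integer(n_outcome_cohort),
    n_individual_cohort = as.integer(n_individual_cohort),
    mafs = mafs, ld_target = ld_target,
    snp_exposure_betas = snp_exposure_betas,
    theta_star = theta_star, exposure_sd = exposure_sd,
    base_case_rate = base_case_rate, mediator_path = mediator_path,
    covariate_effects = covariate_effects,
    seed = as.integer(seed), latent = NULL
  ), class = "sim_config")
}

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation r,
# by 1-D integration of the conditional CDF.
.pbinorm <- function(a, b, r) {
  if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((b - r * z) / sqrt(1 - r^2))
  }, -8.5, a, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# allele correlation of two thresholded latent Gaussians
.threshold_corr <- function(rho_latent, p1, p2) {
  p11 <- .pbinorm(stats::qnorm(p1), stats::qnorm(p2), rho_latent)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

#' Solve the copula's latent correlation for a target dosage LD
#'
#' For each variant pair, finds the latent-Gaussian correlation whose
#' thresholded-haplotype allele correlation equals the target dosage
#' correlation (the dosage, a sum of two independent haplotypes, inherits
#' the haplotype correlation). Solved by root finding per pair; the
#' assembled matrix is floored to positive semidefinite if tiny negative
#' eigenvalues arise.
#'
#' @param ld_target [ld_matrix()] or plain correlation matrix of target
#'   dosage correlations.
#' @param mafs per-variant allele frequencies.
#' @return latent correlation matrix (plain matrix).
#' @export
latent_correlation <- function(ld_target, mafs) {
  rho_t <- if (inherits(ld_target, "ld_matrix")) ld_target$rho else
    as.matrix(ld_target)
  m <- length(mafs)
  stopifnot(nrow(rho_t) == m)
  latent <- diag(m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      target <- rho_t[i, j]
      if (target == 0) next
      lo <- .threshold_corr(-0.9999, mafs[i], mafs[j])
      hi <- .threshold_corr(0.9999, mafs[i], mafs[j])
      if (target <= lo || target >= hi) {
        stop(sprintf(
          "target LD %.3f between variants %d and %d infeasible at MAFs %.3f/%.3f (attainable range %.3f..%.3f)",
          target, i, j, mafs[i], mafs[j], lo, hi), call. = FALSE)
      }
      latent[i, j] <- latent[j, i] <- stats::uniroot(
        function(r) .threshold_corr(r, mafs[i], mafs[j]) - target,
        interval = c(-0.9999, 0.9999), tol = 1e-9)$root
    }
  }
  ev <- eigen(latent, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    latent <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(latent))
    latent <- latent / outer(d, d)
  }
  latent
}

#' Simulate LD-correlated biallelic genotype dosages
#'
#' Draws two haplotypes per person from a Gaussian copula: correlated
#' standard normals thresholded at `qnorm(maf)` give per-haplotype allele
#' indicators, and the dosage is their sum, so dosages lie in {0, 1, 2},
#' empirical allele frequencies approach `mafs` and empirical dosage
#' correlations approach the target LD as n grows.
#'
#' @param n number of individuals.
#' @param mafs per-variant effect-allele frequencies.
#' @param ld_target target dosage-correlation matrix ([ld_matrix()] or
#'   plain matrix); `NULL` for independent variants.
#' @param seed optional integer seed.
#' @param latent optional precomputed [latent_correlation()] matrix (saves
#'   the per-pair root finding in replicate loops).
#' @return n x m integer matrix of dosages, columns named by variant.
#' @export
simulate_genotypes <- function(n, mafs, ld_target = NULL, seed = NULL,
                               latent = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(mafs)
  rsids <- if (inherits(ld_target, "ld_matrix")) ld_target$rsids else
    paste0("snp", seq_len(m))
  if (is.null(latent)) {
    latent <- if (is.null(ld_target)) diag(m) else
      latent_correlation(ld_target, mafs)
  }
  ch <- chol(latent)
  thresholds <- stats::qnorm(mafs)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m) %*% ch
    t(t(z) < thresholds) * 1L
  }
  d <- hap() + hap()
  storage.mode(d) <- "integer"
  colnames(d) <- rsids
  d
}

# Convert per-allele marginal effects (what a GWAS reports and what the
# instrument table prints) into the joint/conditional generative effects
# that reproduce them under the LD-implied dosage covariance
# (Hardy-Weinberg variance 2*maf*(1-maf) per variant).
.conditional_betas <- function(marginal, rho, mafs) {
  sdg <- sqrt(2 * mafs * (1 - mafs))
  sigma_g <- outer(sdg, sdg) * rho
  drop(solve(sigma_g, marginal * sdg^2))
}

# logistic intercept giving the target marginal prevalence
.solve_intercept <- function(lp, target_rate) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target_rate,
                 interval = c(-40, 40), tol = 1e-10)$root
}

#' Simulate exposure, mediator and binary outcome phenotypes
#'
#' The causal model the MR analysis assumes: the exposure is a linear
#' combination of dosages plus Gaussian noise, with joint per-variant
#' effects solved from the configured marginal effects under the target
#' LD; an optional mediator is likewise genetic plus noise; case labels
#' are drawn from a logistic model whose linear predictor is
#' `theta_star * exposure` (plus `beta_co * mediator` when the pleiotropic
#' path is configured) with the intercept solved numerically so the
#' marginal case fraction equals `base_case_rate`. Uses the current RNG
#' stream; seed the caller (or use [simulate_two_sample()] /
#' [simulate_cohort()], which seed from the config).
#'
#' @param dosages n x m dosage matrix.
#' @param config a [sim_config()].
#' @param extra_lp optional extra linear-predictor term (e.g. covariate
#'   effects), length n.
#' @return list with `exposure` (mmHg), `mediator` (or NULL) and `case`
#'   (0/1 vector).
#' @export
simulate_phenotypes <- function(dosages, config, extra_lp = NULL) {
  stopifnot(inherits(config, "sim_config"),
            ncol(dosages) == length(config$mafs))
  n <- nrow(dosages)
  rho <- if (inherits(config$ld_target, "ld_matrix"))
    config$ld_target$rho else as.matrix(config$ld_target)
  # configured effects are marginal per-allele effects; generate from the
  # joint effects that reproduce them under the target LD
  bx_joint <- .conditional_betas(config$snp_exposure_betas, rho,
                                 config$mafs)
  exposure <- drop(dosages %*% bx_joint) +
    stats::rnorm(n, 0, config$exposure_sd)
  mediator <- NULL
  lp <- config$theta_star * exposure
  if (!is.null(config$mediator_path)) {
    mp <- config$mediator_path
    bc_joint <- .conditional_betas(mp$bc, rho, config$mafs)
    mediator <- drop(dosages %*% bc_joint) +
      stats::rnorm(n, 0, mp$mediator_sd)
    lp <- lp + mp$beta_co * mediator
  }
  if (!is.null(extra_lp)) lp <- lp + extra_lp
  alpha <- .solve_intercept(lp, config$base_case_rate)
  case <- stats::rbinom(n, 1L, stats::plogis(alpha + lp))
  list(exposure = exposure, mediator = mediator, case = case)
}

#' Per-variant summary statistics from an individual-level cohort
#'
#' For a continuous trait, per-variant simple linear regression (beta in
#' trait units per allele); for a binary trait, per-variant logistic
#' regression (log-odds per allele). Returns a variant-association table
#' with empirical effect-allele frequencies; dosage columns count the
#' effect allele of `variant_info`. Degenerate (constant-dosage) variants
#' are skipped with a message.
#'
#' @param dosages n x m dosage matrix.
#' @param phenotype numeric trait values (continuous) or 0/1 cases.
#' @param trait `"continuous"` or `"binary"`.
#' @param variant_info variant-association table supplying rsid, chrom,
#'   pos and alleles for the m variants (defaults to [table1_fixture()]
#'   when dimensions match).
#' @return variant-association table, one row per non-degenerate variant.
#' @export
summarize_cohort <- function(dosages, phenotype,
                             trait = c("continuous", "binary"),
                             variant_info = NULL) {
  trait <- match.arg(trait)
  m <- ncol(dosages)
  n <- nrow(dosages)
  stopifnot(length(phenotype) == n)
  if (is.null(variant_info)) {
    t1 <- table1_fixture()
    variant_info <- if (m == nrow(t1)) t1 else
      data.frame(rsid = colnames(dosages) %||% paste0("snp", seq_len(m)),
                 chrom = "4", pos = seq_len(m),
                 effect_allele = "A", other_allele = "G",
                 eaf = NA_real_, beta = NA_real_, se = NA_real_,
                 pvalue = NA_real_, n = n, stringsAsFactors = FALSE)
  }
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    g <- dosages[, j]
    if (stats::var(g) == 0) {
      message("variant ", variant_info$rsid[j],
              " has constant dosage; skipped")
      next
    }
    if (trait == "continuous") {
      gc <- g - mean(g)
      yc <- phenotype - mean(phenotype)
      sxx <- sum(gc^2)
      beta <- sum(gc * yc) / sxx
      resid <- yc - beta * gc
      se <- sqrt(sum(resid^2) / (n - 2) / sxx)
      p <- if (n > 2) 2 * stats::pt(-abs(beta / se), df = n - 2) else
        NA_real_
    } else {
      fit <- stats::glm.fit(cbind(1, g), phenotype,
                            family = stats::binomial())
      beta <- fit$coefficients[2L]
      cov_u <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
      se <- sqrt(cov_u[2L, 2L])
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
    row <- variant_info[j, c("rsid", "chrom", "pos", "effect_allele",
                             "other_allele"), drop = FALSE]
    row$eaf <- mean(g) / 2
    row$beta <- unname(beta)
    row$se <- unname(se)
    row$pvalue <- unname(p)
    row$n <- n
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  validate_assoc(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-sample summary-statistics study
#'
#' Generates disjoint exposure and outcome cohorts (and a mediator cohort
#' when the pleiotropic path is configured) from one genotype pool, so no
#' person contributes to two sources, then summarises each cohort into the
#' per-variant summary statistics the pipeline consumes.
#'
#' @param config a [sim_config()]; `config$seed` controls all randomness.
#' @param variant_info passed to [summarize_cohort()].
#' @return list with `exposure`, `outcome`, optional `mediator`
#'   (variant-association tables), `ld` (the target [ld_matrix()]) and
#'   `config`.
#' @export
simulate_two_sample <- function(config, variant_info = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_med <- if (!is.null(config$mediator_path))
    config$mediator_path$n_mediator_cohort else 0L
  n_total <- config$n_exposure_cohort + config$n_outcome_cohort + n_med
  latent <- config$latent %||%
    latent_correlation(config$ld_target, config$mafs)
  g <- simulate_genotypes(n_total, config$mafs, config$ld_target,
                          latent = latent)
  idx_x <- seq_len(config$n_exposure_cohort)
  idx_y <- config$n_exposure_cohort + seq_len(config$n_outcome_cohort)
  if (is.null(variant_info) &&
      length(config$mafs) == nrow(table1_fixture())) {
    variant_info <- table1_fixture()
    variant_info$eaf <- config$mafs
  }
  ph_x <- simulate_phenotypes(g[idx_x, , drop = FALSE], config)
  ph_y <- simulate_phenotypes(g[idx_y, , drop = FALSE], config)
  out <- list(
    exposure = summarize_cohort(g[idx_x, , drop = FALSE], ph_x$exposure,
                                "continuous", variant_info),
    outcome = summarize_cohort(g[idx_y, , drop = FALSE], ph_y$case,
                               "binary", variant_info),
    ld = if (inherits(config$ld_target, "ld_matrix")) config$ld_target else
      ld_matrix(config$ld_target),
    config = config
  )
  if (n_med > 0L) {
    idx_c <- config$n_exposure_cohort + config$n_outcome_cohort +
      seq_len(n_med)
    ph_c <- simulate_phenotypes(g[idx_c, , drop = FALSE], config)
    out$mediator <- summarize_cohort(g[idx_c, , drop = FALSE],
                                     ph_c$mediator, "continuous",
                                     variant_info)
  }
  out
}

#' Simulate a biobank-like individual-level cohort
#'
#' Generates a cohort table for the sex-stratified stage: genotype dosages,
#' sex (balanced), age at first assessment (normal around 57), genotyping
#' batch (categorical), 10 standard-normal genetic principal components,
#' and dementia-subtype labels. AD case status follows the configured
#' logistic model (including any covariate effects, age centred); a small
#' fraction of non-AD participants is labelled with other dementia forms
#' (defaults vascular 0.7%, frontotemporal 0.2%, other 0.3%, together
#' about the 1.2% the exclusion stage is meant to remove).
#'
#' @param config a [sim_config()].
#' @param other_dementia_rates named rates for `vascular`,
#'   `frontotemporal`, `other` labels among non-AD participants.
#' @param variant_info variant-association table naming the variants;
#'   dosage columns `dosage_<rsid>` count its effect alleles.
#' @return data.frame cohort with attribute `variant_info`.
#' @export
simulate_cohort <- function(config,
                            other_dementia_rates = c(vascular = 0.007,
                                                     frontotemporal = 0.002,
                                                     other = 0.003),
                            variant_info = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_individual_cohort
  if (is.null(variant_info) &&
      length(config$mafs) == nrow(table1_fixture())) {
    variant_info <- table1_fixture()
  }
  rsids <- if (!is.null(variant_info)) variant_info$rsid else
    config$ld_target$rsids
  latent <- config$latent %||%
    latent_correlation(config$ld_target, config$mafs)
  g <- simulate_genotypes(n, config$mafs, config$ld_target,
                          latent = latent)
  colnames(g) <- paste0("dosage_", rsids)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- stats::rnorm(n, 57, 8)
  batch <- sample(paste0("b", 1:3), n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  extra_lp <- rep(0, n)
  ce <- config$covariate_effects
  if (!is.null(ce$age)) extra_lp <- extra_lp + ce$age * (age - mean(age))
  ph <- simulate_phenotypes(g, config, extra_lp = extra_lp)
  label <- ifelse(ph$case == 1L, "AD", "none")
  ctrl <- which(label == "none")
  p_other <- other_dementia_rates
  draw <- stats::runif(length(ctrl))
  cuts <- cumsum(p_other)
  label[ctrl[draw < cuts[1L]]] <- "vascular"
  label[ctrl[draw >= cuts[1L] & draw < cuts[2L]]] <- "frontotemporal"
  label[ctrl[draw >= cuts[2L] & draw < cuts[3L]]] <- "other"
  cohort <- data.frame(id = sprintf("id%06d", seq_len(n)), sex = sex,
                       age = age, batch = batch, pcs, g,
                       dementia_label = label, stringsAsFactors = FALSE)
  attr(cohort, "variant_info") <- variant_info
  cohort
}
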
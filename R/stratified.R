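.dementia_levels <- c("none", "AD", "vascular", "frontotemporal", "other")

#' Exclude non-AD dementia from a cohort
#'
#' Restricts a biobank-like cohort to Alzheimer's disease cases and
#' dementia-free controls by removing persons labelled `vascular`,
#' `frontotemporal` or `other`; removal counts are reported via `message()`.
#'
#' @param cohort data.frame with a `dementia_label` column taking values in
#'   `none`, `AD`, `vascular`, `frontotemporal`, `other`.
#' @return the retained rows.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot("dementia_label" %in% names(cohort))
  bad <- !cohort$dementia_label %in% .dementia_levels
  if (any(bad)) {
    stop("unknown dementia label(s): ",
         paste(unique(cohort$dementia_label[bad]), collapse = ", "),
         call. = FALSE)
  }
  removed <- cohort$dementia_label %in% c("vascular", "frontotemporal",
                                          "other")
  if (any(removed)) {
    counts <- table(cohort$dementia_label[removed])
    message("excluded ", sum(removed), " person(s) with other dementia (",
            paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  out <- cohort[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Firth-type bias-reduced logistic regression: Newton iterations on the
# hat-value-adjusted score. Returns coefficients and SEs for design X.
.firth_logistic <- function(X, y, tol = 1e-8, maxit = 100) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% b))
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * X) * w
    score <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(info_inv %*% score)
    b <- b + delta
    if (max(abs(delta)) < tol) {
      se <- sqrt(diag(info_inv))
      return(list(coef = b, se = se, iter = it, converged = TRUE))
    }
  }
  stop("bias-reduced logistic regression did not converge in ", maxit,
       " iterations", call. = FALSE)
}

#' Per-variant covariate-adjusted logistic regression
#'
#' Fits a maximum-likelihood logistic regression of AD case status on one
#' variant's genotype dosage, adjusting for age, genotyping batch
#' (indicator-coded, first level as reference) and the first 10 genetic
#' principal components when those columns are present in the cohort.
#' Returns the dosage coefficient as a log-odds-per-allele association with
#' its standard error and Wald p-value.
#'
#' Non-convergence raises an error with iteration diagnostics; complete or
#' quasi-complete separation (fitted probabilities numerically 0 or 1) is
#' flagged as an error rather than reported as an estimate. Dosages may be
#' fractional (imputed); no hard-call rounding is applied.
#'
#' @param cohort post-exclusion cohort (see [apply_exclusions()]) with a
#'   `dosage_<rsid>` column; covariate columns `age`, `batch`,
#'   `pc1`..`pc10` are used when present.
#' @param rsid variant identifier.
#' @param sex optional `"female"` or `"male"`; restricts the cohort first.
#' @param bias_reduction use a Firth-type hat-value score adjustment
#'   instead of plain maximum likelihood (default FALSE, the convention of
#'   biobank per-variant analyses; useful in rare-outcome simulations).
#' @return one-row data.frame: `rsid`, `beta` (log-odds per allele), `se`,
#'   `pvalue`, `n`, `eaf` (empirical dosage frequency), `n_cases`.
#' @export
fit_variant_outcome <- function(cohort, rsid, sex = NULL,
                                bias_reduction = FALSE) {
  dcol <- paste0("dosage_", rsid)
  if (!dcol %in% names(cohort)) {
    stop("cohort has no dosage column for ", rsid, call. = FALSE)
  }
  if (!is.null(sex)) {
    stopifnot(sex %in% c("female", "male"))
    cohort <- cohort[cohort$sex == sex, , drop = FALSE]
    if (nrow(cohort) == 0L) {
      stop("no ", sex, " participants in cohort", call. = FALSE)
    }
  }
  if (any(cohort$dementia_label %in% c("vascular", "frontotemporal",
                                       "other"))) {
    stop("cohort contains other-dementia rows; run apply_exclusions() first",
         call. = FALSE)
  }
  y <- as.integer(cohort$dementia_label == "AD")
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  dosage <- cohort[[dcol]]
  if (stats::var(dosage) == 0) {
    stop("dosage for ", rsid, " is constant; no association estimable",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if ("age" %in% names(cohort)) X <- cbind(X, age = cohort$age)
  if ("batch" %in% names(cohort)) {
    b <- factor(cohort$batch)
    if (nlevels(b) > 1L) {
      bm <- stats::model.matrix(~ b)[, -1L, drop = FALSE]
      colnames(bm) <- paste0("batch", levels(b)[-1L])
      X <- cbind(X, bm)
    }
  }
  pcs <- intersect(paste0("pc", 1:10), names(cohort))
  for (pc in pcs) X <- cbind(X, stats::setNames(cohort[pc], pc)[[1L]])
  if (length(pcs)) colnames(X)[(ncol(X) - length(pcs) + 1L):ncol(X)] <- pcs

  if (bias_reduction) {
    fit <- .firth_logistic(X, y)
    beta <- fit$coef[2L]
    se <- fit$se[2L]
  } else {
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (!fit$converged) {
      stop("logistic regression for ", rsid, " did not converge (",
           fit$iter, " iterations, deviance ", format(fit$deviance), ")",
           call. = FALSE)
    }
    if (separated) {
      stop("complete or quasi-complete separation for ", rsid,
           "; no finite estimate", call. = FALSE)
    }
    cov_unscaled <- chol2inv(fit$qr$qr[seq_len(fit$rank),
                                       seq_len(fit$rank), drop = FALSE])
    beta <- fit$coefficients[["dosage"]]
    se <- sqrt(diag(cov_unscaled))[2L]
  }
  z <- beta / se
  data.frame(rsid = rsid, beta = unname(beta), se = unname(se),
             pvalue = 2 * stats::pnorm(-abs(z)), n = nrow(X),
             eaf = mean(dosage) / 2, n_cases = sum(y),
             stringsAsFactors = FALSE)
}

#' Sex-stratified cis-MR from an individual-level cohort
#'
#' The individual-level stage: for each sex, estimate every instrument's
#' association with AD by covariate-adjusted logistic regression
#' ([fit_variant_outcome()]), pair those log-odds associations with the
#' sex-combined exposure summary statistics (the variant-exposure effects
#' are taken as identical in the two sexes), harmonise against the LD
#' matrix, and compute the dose-scaled correlated IVW estimate.
#'
#' Dosage columns are assumed to count the exposure table's effect allele
#' (the convention of [simulate_cohort()]); the alleles attached to the
#' fitted outcome associations come from `exposure_stats`.
#'
#' @param cohort post-exclusion cohort with `sex`, `dementia_label`,
#'   covariates and `dosage_<rsid>` columns.
#' @param exposure_stats variant-association table of variant-exposure
#'   effects for the instruments.
#' @param ld an [ld_matrix()] over the instruments.
#' @param scale_mmhg dose scaling (default 5.5 mmHg).
#' @param bias_reduction passed to [fit_variant_outcome()].
#' @return list with elements `female` and `male` (scaled `mr_estimate`s),
#'   `outcome_stats` (per-sex variant-association tables) and
#'   `case_fraction` (per-sex observed case rates).
#' @export
stratified_mr <- function(cohort, exposure_stats, ld, scale_mmhg = 5.5,
                          bias_reduction = FALSE) {
  validate_assoc(exposure_stats)
  stopifnot(inherits(ld, "ld_matrix"))
  missing_dosage <- setdiff(paste0("dosage_", exposure_stats$rsid),
                            names(cohort))
  if (length(missing_dosage) > 0L) {
    stop("cohort lacks dosage column(s): ",
         paste(missing_dosage, collapse = ", "), call. = FALSE)
  }
  out <- list(outcome_stats = list(), case_fraction = c())
  for (s in c("female", "male")) {
    if (!any(cohort$sex == s)) {
      stop("cohort contains no ", s, " participants; cannot run the ", s,
           " analysis", call. = FALSE)
    }
    fits <- do.call(rbind, lapply(exposure_stats$rsid, function(r) {
      fit_variant_outcome(cohort, r, sex = s,
                          bias_reduction = bias_reduction)
    }))
    outcome <- exposure_stats
    outcome$beta <- fits$beta
    outcome$se <- fits$se
    outcome$pvalue <- fits$pvalue
    outcome$n <- fits$n
    outcome$eaf <- fits$eaf
    cf <- fits$n_cases[1L] / fits$n[1L]
    message(sprintf("%s: %d participants, %d cases (%.2f%%)", s,
                    fits$n[1L], fits$n_cases[1L], 100 * cf))
    h <- harmonise(exposure_stats, outcome, ld)
    est <- scale_estimate(mr_ivw_correlated(h,
                                            analysis_id = paste0("stratified_", s)),
                          scale_mmhg)
    out[[s]] <- est
    out$outcome_stats[[s]] <- outcome
    out$case_fraction[s] <- cf
  }
  out
}
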
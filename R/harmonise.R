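.complement <- c(A = "T", T = "A", C = "G", G = "C")

.comp_alleles <- function(a) {
  paste(.complement[strsplit(a, "")[[1L]]], collapse = "")
}

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1L && nchar(oa) == 1L && .complement[[ea]] == oa
}

#' Flip the effect-allele convention of variant records
#'
#' Swaps effect and other allele, negates beta, and complements the
#' effect-allele frequency; `se`, `pvalue` and `n` are unchanged. Applying
#' it twice is the identity.
#'
#' @param record one or more rows of a variant-association table.
#' @return the records on the opposite allele convention.
#' @export
flip_variant <- function(record) {
  validate_assoc(record)
  out <- record
  out$effect_allele <- record$other_allele
  out$other_allele <- record$effect_allele
  out$beta <- -record$beta
  out$eaf <- 1 - record$eaf
  out
}

# Align one source row to the target allele pair (ea, oa).
# Returns list(row, flipped, strand_relabelled) or a character exclusion
# reason. eaf_ref is the target-side EAF used for palindromic resolution.
.align_to_pair <- function(row, ea, oa, palindromic, eaf_threshold,
                           strand_flip, eaf_ref) {
  if (.is_palindromic(ea, oa)) {
    if (palindromic == "drop") return("palindromic_ambiguous")
    ok_pair <- (row$effect_allele == ea && row$other_allele == oa) ||
      (row$effect_allele == oa && row$other_allele == ea)
    if (!ok_pair) return("allele_mismatch")
    maf_ref <- pmin(eaf_ref, 1 - eaf_ref)
    maf_row <- pmin(row$eaf, 1 - row$eaf)
    if (is.na(maf_ref) || is.na(maf_row) ||
        maf_ref >= eaf_threshold || maf_row >= eaf_threshold) {
      return("palindromic_ambiguous")
    }
    flipped <- FALSE
    if (row$effect_allele == oa) {
      row <- flip_variant(row); flipped <- TRUE
    }
    # strand check: minor allele must agree with the reference side
    if ((row$eaf < 0.5) != (eaf_ref < 0.5)) {
      row <- flip_variant(row); flipped <- !flipped
    }
    return(list(row = row, flipped = flipped, strand_relabelled = FALSE))
  }
  if (row$effect_allele == ea && row$other_allele == oa) {
    return(list(row = row, flipped = FALSE, strand_relabelled = FALSE))
  }
  if (row$effect_allele == oa && row$other_allele == ea) {
    return(list(row = flip_variant(row), flipped = TRUE,
                strand_relabelled = FALSE))
  }
  if (strand_flip) {
    cea <- .comp_alleles(row$effect_allele)
    coa <- .comp_alleles(row$other_allele)
    if (cea == ea && coa == oa) {
      row$effect_allele <- cea; row$other_allele <- coa
      return(list(row = row, flipped = FALSE, strand_relabelled = TRUE))
    }
    if (cea == oa && coa == ea) {
      row$effect_allele <- cea; row$other_allele <- coa
      return(list(row = flip_variant(row), flipped = TRUE,
                  strand_relabelled = TRUE))
    }
  }
  "allele_mismatch"
}

#' Harmonise exposure, outcome, mediator and LD allele conventions
#'
#' Expresses every source's beta and allele frequency on a single effect
#' allele per variant so that downstream estimation is well defined. The
#' anchor allele is the LD matrix's recorded reference allele where known,
#' and the exposure's effect allele otherwise. Outcome and mediator rows
#' whose allele pair matches the exposure's in neither orientation (after
#' an optional strand relabelling) are excluded with reason
#' `"allele_mismatch"`; palindromic (A/T, C/G) variants are resolved by
#' allele-frequency concordance when the minor-allele frequency is below
#' `eaf_threshold` on both sides, and excluded as
#' `"palindromic_ambiguous"` otherwise. Variants absent from a mandatory
#' source are excluded with reason `"missing"`, never silently dropped.
#'
#' When a variant's anchor switches relative to the LD matrix's convention,
#' the corresponding LD row and column signs are flipped so the matrix
#' stays internally consistent.
#'
#' @param exposure,outcome variant-association tables (exposure in trait
#'   units, outcome in log-odds).
#' @param ld an [ld_matrix()] covering the instruments.
#' @param mediator optional variant-association table for a mediating trait.
#' @param palindromic `"eaf"` (resolve palindromic variants by frequency
#'   concordance; default) or `"drop"` (exclude all palindromic variants).
#' @param eaf_threshold maximum minor-allele frequency at which a
#'   palindromic variant is considered resolvable (default 0.42).
#' @param strand_flip attempt complementary-strand relabelling before
#'   declaring an allele mismatch (default TRUE; every application logged).
#' @return object of class `harmonised_set`: list with `rsids`,
#'   `effect_allele`, `other_allele`, `bx`, `sx`, `eaf_x`, `by`, `sy`,
#'   `eaf_y`, optional `bc`, `sc`, `ld` (aligned), `flips` (log of every
#'   orientation change) and `exclusions` (rsid + reason).
#' @export
harmonise <- function(exposure, outcome, ld, mediator = NULL,
                      palindromic = c("eaf", "drop"), eaf_threshold = 0.42,
                      strand_flip = TRUE) {
  palindromic <- match.arg(palindromic)
  validate_assoc(exposure)
  validate_assoc(outcome)
  stopifnot(inherits(ld, "ld_matrix"))
  if (!is.null(mediator)) validate_assoc(mediator)
  if (anyDuplicated(exposure$rsid)) stop("duplicated rsid in exposure",
                                         call. = FALSE)

  rsids <- exposure$rsid
  flips <- data.frame(rsid = character(), source = character(),
                      action = character(), stringsAsFactors = FALSE)
  exclusions <- data.frame(rsid = character(), reason = character(),
                           stringsAsFactors = FALSE)
  note_flip <- function(rsid, source, action) {
    flips <<- rbind(flips, data.frame(rsid = rsid, source = source,
                                      action = action))
  }
  kept <- list()

  for (rsid in rsids) {
    xr <- exposure[exposure$rsid == rsid, , drop = FALSE]
    if (!rsid %in% outcome$rsid || !rsid %in% ld$rsids ||
        (!is.null(mediator) && !rsid %in% mediator$rsid)) {
      exclusions <- rbind(exclusions, data.frame(rsid = rsid,
                                                 reason = "missing"))
      next
    }
    yr <- outcome[outcome$rsid == rsid, , drop = FALSE][1L, ]
    j <- match(rsid, ld$rsids)

    # anchor the variant on the LD reference allele when recorded
    anchor <- ld$ref_alleles[j]
    ld_sign <- 1
    if (!is.na(anchor) && anchor != xr$effect_allele) {
      if (anchor == xr$other_allele) {
        xr <- flip_variant(xr)
        note_flip(rsid, "exposure", "flip_to_ld_anchor")
      } else if (strand_flip &&
                 .comp_alleles(xr$effect_allele) == anchor) {
        xr$effect_allele <- .comp_alleles(xr$effect_allele)
        xr$other_allele <- .comp_alleles(xr$other_allele)
        note_flip(rsid, "exposure", "strand_relabel")
      } else if (strand_flip &&
                 .comp_alleles(xr$other_allele) == anchor) {
        xr$effect_allele <- .comp_alleles(xr$effect_allele)
        xr$other_allele <- .comp_alleles(xr$other_allele)
        xr <- flip_variant(xr)
        note_flip(rsid, "exposure", "strand_relabel_flip")
      } else {
        exclusions <- rbind(exclusions,
                            data.frame(rsid = rsid,
                                       reason = "allele_mismatch"))
        next
      }
      if (xr$effect_allele != anchor) {
        # flipped onto the non-anchor allele: negate the LD row instead
        ld_sign <- -1
      }
    }

    aligned_y <- .align_to_pair(yr, xr$effect_allele, xr$other_allele,
                                palindromic, eaf_threshold, strand_flip,
                                eaf_ref = xr$eaf)
    if (is.character(aligned_y)) {
      exclusions <- rbind(exclusions, data.frame(rsid = rsid,
                                                 reason = aligned_y))
      next
    }
    if (aligned_y$strand_relabelled) note_flip(rsid, "outcome",
                                               "strand_relabel")
    if (aligned_y$flipped) note_flip(rsid, "outcome", "flip")

    cr <- NULL
    if (!is.null(mediator)) {
      mr_row <- mediator[mediator$rsid == rsid, , drop = FALSE][1L, ]
      aligned_c <- .align_to_pair(mr_row, xr$effect_allele, xr$other_allele,
                                  palindromic, eaf_threshold, strand_flip,
                                  eaf_ref = xr$eaf)
      if (is.character(aligned_c)) {
        exclusions <- rbind(exclusions, data.frame(rsid = rsid,
                                                   reason = aligned_c))
        next
      }
      if (aligned_c$strand_relabelled) note_flip(rsid, "mediator",
                                                 "strand_relabel")
      if (aligned_c$flipped) note_flip(rsid, "mediator", "flip")
      cr <- aligned_c$row
    }

    kept[[rsid]] <- list(x = xr, y = aligned_y$row, c = cr,
                         ld_sign = ld_sign)
  }

  kept_ids <- names(kept)
  if (length(kept_ids) + nrow(exclusions) != length(rsids)) {
    stop("internal error: variants neither kept nor excluded", call. = FALSE)
  }
  if (length(kept_ids) == 0L) {
    stop("no variants survive harmonisation; exclusions: ",
         paste(exclusions$reason, collapse = ", "), call. = FALSE)
  }

  sub <- ld_subset(ld, kept_ids)
  signs <- vapply(kept[kept_ids], function(k) k$ld_sign, numeric(1L))
  rho <- sweep(sweep(sub$rho, 1L, signs, `*`), 2L, signs, `*`)
  diag(rho) <- 1
  get <- function(field, source) {
    unname(vapply(kept[kept_ids], function(k) {
      v <- k[[source]]
      if (is.null(v)) NA_real_ else as.numeric(v[[field]])
    }, numeric(1L)))
  }
  get_chr <- function(field) {
    unname(vapply(kept[kept_ids], function(k) k$x[[field]], character(1L)))
  }
  out <- list(
    rsids = kept_ids,
    effect_allele = get_chr("effect_allele"),
    other_allele = get_chr("other_allele"),
    bx = get("beta", "x"), sx = get("se", "x"), eaf_x = get("eaf", "x"),
    by = get("beta", "y"), sy = get("se", "y"), eaf_y = get("eaf", "y"),
    ld = ld_matrix(rho, rsids = kept_ids,
                   ref_alleles = get_chr("effect_allele")),
    flips = flips,
    exclusions = exclusions
  )
  if (!is.null(mediator)) {
    out$bc <- get("beta", "c")
    out$sc <- get("se", "c")
  }
  structure(out, class = "harmonised_set")
}

#' Build a harmonised set directly from aligned vectors
#'
#' Convenience constructor for simulation studies and toy examples where
#' all sources are already on a common allele convention.
#'
#' @param bx,sx exposure betas and standard errors.
#' @param by,sy outcome betas (log-odds) and standard errors.
#' @param rho LD correlation matrix (defaults to identity).
#' @param rsids variant identifiers.
#' @param bc,sc optional mediator betas and standard errors.
#' @return a `harmonised_set`.
#' @export
harmonised_set <- function(bx, sx, by, sy, rho = diag(length(bx)),
                           rsids = paste0("snp", seq_along(bx)),
                           bc = NULL, sc = NULL) {
  stopifnot(length(bx) == length(by))
  sx <- rep_len(sx, length(bx))
  sy <- rep_len(sy, length(bx))
  out <- list(rsids = rsids,
              effect_allele = rep(NA_character_, length(bx)),
              other_allele = rep(NA_character_, length(bx)),
              bx = as.numeric(bx), sx = as.numeric(sx),
              eaf_x = rep(NA_real_, length(bx)),
              by = as.numeric(by), sy = as.numeric(sy),
              eaf_y = rep(NA_real_, length(bx)),
              ld = ld_matrix(rho, rsids = rsids),
              flips = data.frame(rsid = character(), source = character(),
                                 action = character()),
              exclusions = data.frame(rsid = character(),
                                      reason = character()))
  if (!is.null(bc)) {
    stopifnot(length(bc) == length(bx), length(sc) == length(bx))
    out$bc <- as.numeric(bc)
    out$sc <- as.numeric(sc)
  }
  structure(out, class = "harmonised_set")
}

# restrict a harmonised set to a subset of variants (used by leave-one-out)
.h_subset <- function(h, keep_idx) {
  out <- h
  for (field in c("rsids", "effect_allele", "other_allele", "bx", "sx",
                  "eaf_x", "by", "sy", "eaf_y", "bc", "sc")) {
    if (!is.null(out[[field]])) out[[field]] <- out[[field]][keep_idx]
  }
  out$ld <- ld_subset(h$ld, h$rsids[keep_idx])
  out
}
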
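#' Define a cis region
#'
#' A cis region restricts instruments to variants within (a flank around)
#' the gene encoding the drug target, e.g. PDE5A at chr4:120,415,550-
#' 120,550,146 (GRCh37).
#'
#' @param chrom chromosome label (e.g. `"4"`).
#' @param start,end 1-based GRCh37 bounds, `start <= end`.
#' @param flank_kb kilobases of flank added to each side (default 0).
#' @return object of class `cis_region`.
#' @export
cis_region <- function(chrom, start, end, flank_kb = 0) {
  stopifnot(length(chrom) == 1L, start <= end, flank_kb >= 0)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), flank_kb = as.numeric(flank_kb)),
            class = "cis_region")
}

#' Filter variants to a cis region
#'
#' Retains variants on the region's chromosome with position inside
#' `[start - flank, end + flank]`, bounds inclusive.
#'
#' @param records variant-association table.
#' @param region a [cis_region()].
#' @return the retained rows of `records`.
#' @export
filter_cis <- function(records, region) {
  stopifnot(inherits(region, "cis_region"))
  validate_assoc(records)
  flank <- region$flank_kb * 1000
  keep <- records$chrom == region$chrom &
    records$pos >= region$start - flank &
    records$pos <= region$end + flank
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("no variants inside cis region")
  rownames(out) <- NULL
  out
}

#' Filter variants by association p-value
#'
#' Retains variants with p-value strictly below the threshold (the
#' genome-wide significance convention, p < 5e-8, by default).
#'
#' @param records variant-association table.
#' @param p_threshold retain rows with `pvalue < p_threshold`.
#' @return the retained rows of `records`.
#' @export
filter_significance <- function(records, p_threshold = 5e-8) {
  validate_assoc(records)
  out <- records[!is.na(records$pvalue) & records$pvalue < p_threshold, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy p-value-priority LD clumping
#'
#' Repeatedly takes the remaining variant with the lowest p-value as an
#' index and removes all remaining variants within `window_kb` of it whose
#' squared correlation with it is at or above `r2_threshold`. Survivors
#' therefore have all pairwise r-squared below the threshold within any
#' window. Ties on p-value are broken by lower position, then lexicographic
#' rsid, so the output is invariant to input row order.
#'
#' @param records variant-association table (exposure scale; `pvalue` used
#'   for priority).
#' @param ld an [ld_matrix()] covering every record.
#' @param r2_threshold squared-correlation threshold; a candidate with
#'   `r^2 >= r2_threshold` to a retained index variant is removed.
#' @param window_kb window half-width in kilobases around each index
#'   variant; LD pruning only applies within the window.
#' @return object of class `instrument_set`: list with `variants` (the
#'   retained rows, in selection order), `f_stats` (per-variant
#'   `(beta/se)^2`), `ld` (the LD matrix restricted and aligned to the
#'   survivors) and `provenance` (the thresholds used).
#' @export
clump <- function(records, ld, r2_threshold = 0.35, window_kb = 10000) {
  validate_assoc(records)
  stopifnot(inherits(ld, "ld_matrix"))
  missing_ids <- setdiff(records$rsid, ld$rsids)
  if (length(missing_ids) > 0L) {
    stop("variant(s) missing from LD matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ord <- order(records$pvalue, records$pos, records$rsid)
  pool <- records[ord, , drop = FALSE]
  kept <- character(0)
  while (nrow(pool) > 0L) {
    index <- pool[1L, ]
    kept <- c(kept, index$rsid)
    pool <- pool[-1L, , drop = FALSE]
    if (nrow(pool) > 0L) {
      in_window <- abs(pool$pos - index$pos) <= window_kb * 1000
      r <- ld$rho[match(pool$rsid, ld$rsids), match(index$rsid, ld$rsids)]
      pool <- pool[!(in_window & r^2 >= r2_threshold), , drop = FALSE]
    }
  }
  variants <- records[match(kept, records$rsid), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(
    variants = variants,
    f_stats = stats::setNames(f_statistic(variants$beta, variants$se), kept),
    ld = ld_subset(ld, kept),
    provenance = list(r2_threshold = r2_threshold, window_kb = window_kb)
  ), class = "instrument_set")
}

#' Per-variant instrument strength (F-statistic)
#'
#' The default method is the squared Wald statistic `(beta/se)^2`, the
#' single-variant form of the Cragg-Donald F-statistic. The
#' variance-explained method computes `R2 = 2*eaf*(1-eaf)*beta^2 /
#' var_phenotype` and returns `(n - 2) * R2 / (1 - R2)`; the two agree when
#' `R2 = chi2 / (chi2 + n - 2)` with `chi2 = (beta/se)^2`.
#'
#' @param beta,se per-allele effect and standard error (vectorised).
#' @param method `"wald"` (default) or `"variance_explained"`.
#' @param eaf,n,var_phenotype required for the variance-explained method:
#'   effect-allele frequency, sample size, and phenotype variance in
#'   squared trait units.
#' @return numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se, method = c("wald", "variance_explained"),
                        eaf = NULL, n = NULL, var_phenotype = NULL) {
  method <- match.arg(method)
  if (any(se == 0)) stop("se = 0: F-statistic undefined", call. = FALSE)
  if (method == "wald") return((beta / se)^2)
  if (is.null(eaf) || is.null(n) || is.null(var_phenotype)) {
    stop("variance-explained method needs eaf, n and var_phenotype",
         call. = FALSE)
  }
  if (any(var_phenotype <= 0)) stop("var_phenotype must be positive",
                                    call. = FALSE)
  r2 <- 2 * eaf * (1 - eaf) * beta^2 / var_phenotype
  (n - 2) * r2 / (1 - r2)
}
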
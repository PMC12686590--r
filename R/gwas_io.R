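#' @keywords internal
"_PACKAGE"

# Canonical column order for a variant-association table.
.assoc_cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")

#' Validate a variant-association table
#'
#' A variant-association table holds one row per variant: identifier,
#' chromosome, GRCh37 1-based position, effect/other allele, effect-allele
#' frequency, per-effect-allele beta (mmHg for a continuous exposure,
#' log-odds for a binary outcome), its standard error, p-value and sample
#' size. Alleles must be uppercase A/C/G/T and distinct; `se` must be
#' positive; `eaf` may be `NA` (flagged downstream) but otherwise lies in
#' [0, 1].
#'
#' @param x data.frame with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @return `x`, invisibly, with columns in canonical order.
#' @export
validate_assoc <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.assoc_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("variant-association table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, .assoc_cols, drop = FALSE]
  if (nrow(x) == 0L) return(invisible(x))
  bad_allele <- !grepl("^[ACGT]+$", x$effect_allele) |
    !grepl("^[ACGT]+$", x$other_allele)
  if (any(bad_allele)) {
    stop("non-ACGT or lowercase allele for: ",
         paste(x$rsid[bad_allele], collapse = ", "), call. = FALSE)
  }
  if (any(x$effect_allele == x$other_allele)) {
    stop("effect and other allele identical for: ",
         paste(x$rsid[x$effect_allele == x$other_allele], collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(x$se) & x$se <= 0)) {
    stop("non-positive standard error for: ",
         paste(x$rsid[!is.na(x$se) & x$se <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))) {
    stop("effect-allele frequency outside [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-ed delimited file of per-variant summary statistics into a
#' canonical variant-association table. Header names in the wild vary across
#' consortia, so a `column_map` translates them; the default matches the
#' columns `SNP/CHR/POS/EA/OA/EAF/BETA/SE/P/N`.
#'
#' Rows with missing beta or standard error are dropped with a message
#' counting them. Alleles are uppercased. Coordinates are taken as GRCh37,
#' 1-based; no liftover is performed.
#'
#' @param path file path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical field names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's header names. Fields `eaf`
#'   and `n` are optional; all others are required.
#' @param delim field delimiter, `"\t"` (default) or `","`.
#' @return data.frame, one row per variant (see [validate_assoc()]).
#' @export
read_summary_stats <- function(path,
                               column_map = default_column_map(),
                               delim = "\t") {
  stopifnot(delim %in% c("\t", ","))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  required <- setdiff(.assoc_cols, c("eaf", "n"))
  for (field in required) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("required column '", field, "' (file header '",
           if (is.null(col)) "?" else col, "') not found in ", path,
           call. = FALSE)
    }
  }
  pick <- function(field) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[col]]
  }
  parse_num <- function(field, required_field = FALSE) {
    chr <- pick(field)
    val <- suppressWarnings(as.numeric(chr))
    bad <- !is.na(chr) & chr != "" & chr != "NA" & is.na(val)
    if (required_field && any(bad)) {
      stop("non-numeric value for '", field, "' at data line ",
           which(bad)[1L], " of ", path, call. = FALSE)
    }
    val
  }
  out <- data.frame(
    rsid = pick("rsid"),
    chrom = as.character(pick("chrom")),
    pos = parse_num("pos", TRUE),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    eaf = parse_num("eaf"),
    beta = parse_num("beta", TRUE),
    se = parse_num("se", TRUE),
    pvalue = parse_num("pvalue", TRUE),
    n = parse_num("n"),
    stringsAsFactors = FALSE
  )
  drop <- is.na(out$beta) | is.na(out$se)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing beta or se dropped from ", path)
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  validate_assoc(out)
  out
}

#' Default header mapping for summary statistics
#'
#' @return named character vector mapping canonical field names to the
#'   `SNP/CHR/POS/EA/OA/EAF/BETA/SE/P/N` header dialect.
#' @export
default_column_map <- function() {
  c(rsid = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
    pvalue = "P", n = "N")
}

#' Write GWAS summary statistics as TSV
#'
#' Inverse of [read_summary_stats()] under the default column map.
#'
#' @param x variant-association table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  x <- as.data.frame(validate_assoc(x))
  map <- default_column_map()
  out <- x[, .assoc_cols, drop = FALSE]
  names(out) <- unname(map[.assoc_cols])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an LD correlation matrix object
#'
#' Holds the signed pairwise allele-dosage correlations among a set of
#' variants, together with the allele each row's sign convention is anchored
#' to. The matrix must be symmetric with a unit diagonal and (near)
#' positive semidefinite.
#'
#' @param rho square numeric matrix of signed correlations in [-1, 1].
#' @param rsids variant identifiers, one per row/column.
#' @param ref_alleles the effect allele each row's dosage is counted on;
#'   `NA` when the anchoring convention is unknown.
#' @param tol eigenvalue tolerance for the positive-semidefinite check.
#' @return object of class `ld_matrix` with elements `rsids`, `rho`,
#'   `ref_alleles`.
#' @export
ld_matrix <- function(rho, rsids = rownames(rho),
                      ref_alleles = rep(NA_character_, length(rsids)),
                      tol = 1e-6) {
  rho <- as.matrix(rho)
  m <- nrow(rho)
  if (ncol(rho) != m) stop("LD matrix must be square", call. = FALSE)
  if (is.null(rsids) || length(rsids) != m) {
    stop("rsids must name every row of the LD matrix", call. = FALSE)
  }
  if (length(ref_alleles) != m) {
    stop("ref_alleles must have one entry per variant", call. = FALSE)
  }
  if (any(abs(rho) > 1 + 1e-12)) {
    stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (max(abs(rho - t(rho))) > 1e-8) {
    stop("LD matrix is not symmetric within 1e-8", call. = FALSE)
  }
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("LD matrix is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  dimnames(rho) <- list(rsids, rsids)
  structure(list(rsids = as.character(rsids), rho = rho,
                 ref_alleles = toupper(as.character(ref_alleles))),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Expects a square numeric table whose header row and first column are the
#' variant identifiers. The matrix is symmetrised as (M + t(M))/2 provided
#' the asymmetry is within 1e-8, and the diagonal is set to one.
#'
#' The sign convention of the off-diagonal correlations depends on which
#' allele each row's dosage was counted on; supply `ref_alleles` explicitly
#' when known rather than assuming an anchoring.
#'
#' @param path file path.
#' @param ref_alleles optional anchor alleles, in the file's variant order
#'   or named by rsid.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path, ref_alleles = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(raw)
  if (nrow(mat) != ncol(mat)) {
    stop("LD matrix file is not square: ", nrow(mat), " rows, ",
         ncol(mat), " columns", call. = FALSE)
  }
  if (!is.numeric(mat)) stop("LD matrix contains non-numeric cells",
                             call. = FALSE)
  off <- mat[upper.tri(mat) | lower.tri(mat)]
  if (any(abs(off) > 1)) {
    stop("off-diagonal |r| > 1 in ", path, call. = FALSE)
  }
  rsids <- rownames(mat)
  if (!identical(rsids, colnames(mat))) {
    # accept permuted columns if the same identifiers are present
    if (!setequal(rsids, colnames(mat))) {
      stop("row and column identifiers differ in ", path, call. = FALSE)
    }
    mat <- mat[, rsids, drop = FALSE]
  }
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-4) {
    stop("LD matrix asymmetry ", format(asym), " too large to average",
         call. = FALSE)
  }
  mat <- (mat + t(mat)) / 2
  ra <- rep(NA_character_, length(rsids))
  if (!is.null(ref_alleles)) {
    ra <- if (!is.null(names(ref_alleles))) {
      unname(ref_alleles[rsids])
    } else ref_alleles
  }
  ld_matrix(mat, rsids, ra)
}

#' Write an LD matrix as TSV
#'
#' @param ld an [ld_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- as.data.frame(ld$rho)
  utils::write.table(cbind(rsid = ld$rsids, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict and reorder an LD matrix to a set of variants
#'
#' @param ld an [ld_matrix()].
#' @param rsids identifiers to keep, in the desired order.
#' @return an [ld_matrix()] over exactly `rsids`, in order.
#' @export
ld_subset <- function(ld, rsids) {
  stopifnot(inherits(ld, "ld_matrix"))
  missing_ids <- setdiff(rsids, ld$rsids)
  if (length(missing_ids) > 0L) {
    stop("variant(s) absent from LD matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  idx <- match(rsids, ld$rsids)
  ld_matrix(ld$rho[idx, idx, drop = FALSE], rsids = ld$rsids[idx],
            ref_alleles = ld$ref_alleles[idx])
}

#' Write MR estimates as a result table with JSON sidecar
#'
#' Writes a TSV with columns `analysis_id`, `n_snps`, `beta`, `se`, `or`,
#' `ci_low`, `ci_high`, `pvalue`, `scale_mmhg` (one row per estimate) and a
#' machine-readable JSON sidecar at `<path>.json` preserving full precision.
#'
#' @param estimates list of `mr_estimate` objects (see [mr_ivw_correlated()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    stopifnot(inherits(e, "mr_estimate"))
    data.frame(analysis_id = e$analysis_id, n_snps = e$n_snps,
               beta = e$theta, se = e$se_theta, or = exp(e$theta),
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               scale_mmhg = if (is.null(e$scale_mmhg)) NA_real_ else e$scale_mmhg,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(analysis_id = character(), n_snps = integer(),
               beta = numeric(), se = numeric(), or = numeric(),
               ci_low = numeric(), ci_high = numeric(), pvalue = numeric(),
               scale_mmhg = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- lapply(estimates, unclass)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read the JSON sidecar written by [write_results()]
#'
#' @param path the TSV path passed to [write_results()] (the sidecar lives
#'   at `<path>.json`).
#' @return list of `mr_estimate` objects with full float precision.
#' @export
read_results_sidecar <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(sidecar, function(e) {
    e[vapply(e, is.null, logical(1L))] <- NA
    structure(e, class = "mr_estimate")
  })
}
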
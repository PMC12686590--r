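# 32-bit FNV-1a hash of the deparsed config (multiplication by the FNV
# prime done in 16-bit pieces to stay exact in double precision)
.config_hash <- function(config) {
  bytes <- as.integer(charToRaw(paste(deparse(config), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # h * 16777619 mod 2^32, split to stay within double precision
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read an individual-level cohort table from TSV
#'
#' One row per person; expects `id`, `sex`, `age`, `batch`, `pc1`..`pc10`,
#' `dementia_label` and `dosage_<rsid>` columns.
#'
#' @param path file path.
#' @return data.frame cohort.
#' @export
read_cohort <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("sex", "dementia_label") %in% names(x)))
  x
}

#' Write an individual-level cohort table as TSV
#'
#' @param cohort data.frame cohort.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the cis-MR pipeline end to end
#'
#' Orchestrates simulate/load -> instrument selection -> harmonisation ->
#' estimation -> sensitivity analyses from a single configuration, writing
#' per-analysis result tables (TSV + JSON sidecar), a combined
#' forest-plot-ready table, a structured log, and a run manifest (package
#' version, seed, config hash).
#'
#' @param config a list, or the path to a YAML file, with elements:
#'   * `out_dir` (required), `seed` (default 20251013),
#'     `scale_mmhg` (default 5.5),
#'   * `analyses`: subset of `"main"`, `"loo"`, `"two_step"`, `"pqtl"`,
#'     `"stratified"` (default `"main"`),
#'   * inputs: either `simulate = TRUE` plus optional `sim` overrides for
#'     [sim_config()], or file paths `exposure`, `outcome`, `ld`, and
#'     optionally `mediator`, `cohort`,
#'   * selection: optional `region` (chrom/start/end/flank_kb),
#'     `p_threshold`, `r2` (default 0.35), `window_kb` (default 10000),
#'     `clump` (default TRUE),
#'   * `mediator_effect`: list(beta, se) for the two-step analysis,
#'   * `pqtl_exposure`, `pqtl_outcome`: paths for the uncorrelated pQTL
#'     analysis,
#'   * `resume`: skip the run when the output manifest already matches
#'     this config (default FALSE).
#' @return named list of `mr_estimate` objects (plus `loo` and
#'   `stratified` sublists), invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  analyses <- config$analyses %||% "main"
  bad <- setdiff(analyses, c("main", "loo", "two_step", "pqtl",
                             "stratified"))
  if (length(bad) > 0L) stop("unknown analysis: ",
                             paste(bad, collapse = ", "), call. = FALSE)
  if (length(analyses) == 0L) stop("no analysis requested", call. = FALSE)
  seed <- config$seed %||% 20251013
  scale_mmhg <- config$scale_mmhg %||% 5.5
  out_dir <- config$out_dir
  hash <- .config_hash(config[setdiff(names(config),
                                      c("out_dir", "resume"))])
  manifest_path <- file.path(out_dir, "manifest.json")
  if (isTRUE(config$resume) && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, hash)) {
      message("resume: manifest matches config hash ", hash,
              "; nothing to do")
      return(invisible(NULL))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "log.txt"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  stage <- "load_inputs"
  results <- list()
  tryCatch({
    if (isTRUE(config$simulate) || !is.null(config$sim)) {
      cfg <- do.call(sim_config, c(config$sim %||% list(),
                                   list(seed = seed)))
      sim <- simulate_two_sample(cfg)
      exposure <- sim$exposure; outcome <- sim$outcome
      ld <- sim$ld; mediator <- sim$mediator
      cohort <- if ("stratified" %in% analyses) {
        apply_exclusions(simulate_cohort(cfg))
      } else NULL
      .log_line(log_con, stage, sprintf(
        "simulated inputs: %d instruments, seed %d", nrow(exposure), seed))
    } else {
      exposure <- read_summary_stats(config$exposure)
      outcome <- read_summary_stats(config$outcome)
      ld <- read_ld_matrix(config$ld,
                           ref_alleles = stats::setNames(
                             exposure$effect_allele, exposure$rsid))
      mediator <- if (!is.null(config$mediator))
        read_summary_stats(config$mediator) else NULL
      cohort <- if (!is.null(config$cohort))
        apply_exclusions(read_cohort(config$cohort)) else NULL
      .log_line(log_con, stage, sprintf(
        "read %d exposure and %d outcome variants", nrow(exposure),
        nrow(outcome)))
    }

    stage <- "instrument_selection"
    n0 <- nrow(exposure)
    if (!is.null(config$region)) {
      r <- config$region
      exposure <- filter_cis(exposure,
                             cis_region(r$chrom, r$start, r$end,
                                        r$flank_kb %||% 0))
    }
    if (!is.null(config$p_threshold)) {
      exposure <- filter_significance(exposure, config$p_threshold)
    }
    if (config$clump %||% TRUE) {
      iset <- clump(exposure, ld, config$r2 %||% 0.35,
                    config$window_kb %||% 10000)
      exposure <- iset$variants
    }
    .log_line(log_con, stage, sprintf("%d -> %d instruments", n0,
                                      nrow(exposure)))

    stage <- "harmonisation"
    h <- harmonise(exposure, outcome, ld, mediator = mediator)
    if (nrow(h$exclusions) > 0L) {
      .log_line(log_con, stage, paste("excluded:",
        paste(h$exclusions$rsid, h$exclusions$reason, sep = ":",
              collapse = ", ")))
    }
    .log_line(log_con, stage, sprintf("%d instruments harmonised",
                                      length(h$rsids)))

    if ("main" %in% analyses) {
      stage <- "main"
      results$main <- scale_estimate(mr_ivw_correlated(h), scale_mmhg)
      write_results(list(results$main), file.path(out_dir, "main.tsv"))
      .log_line(log_con, stage, sprintf(
        "scaled OR %.4f [%.4f, %.4f]", results$main$scaled_or,
        results$main$scaled_ci_low, results$main$scaled_ci_high))
    }
    if ("loo" %in% analyses) {
      stage <- "leave_one_out"
      results$loo <- leave_one_out(h, scale_mmhg)
      write_results(results$loo, file.path(out_dir, "leave_one_out.tsv"))
      .log_line(log_con, stage, sprintf("%d re-estimates",
                                        length(results$loo)))
    }
    if ("two_step" %in% analyses) {
      stage <- "two_step"
      me <- config$mediator_effect
      if (is.null(me)) stop("two_step requires config$mediator_effect")
      est <- two_step_mr(h, mediator_effect(me$beta, me$se))
      results$two_step <- scale_estimate(est, scale_mmhg)
      write_results(list(results$two_step),
                    file.path(out_dir, "two_step.tsv"))
      .log_line(log_con, stage, sprintf("adjusted theta %.4g",
                                        results$two_step$theta))
    }
    if ("pqtl" %in% analyses) {
      stage <- "pqtl"
      if (is.null(config$pqtl_exposure) || is.null(config$pqtl_outcome)) {
        stop("pqtl requires config$pqtl_exposure and config$pqtl_outcome")
      }
      px <- read_summary_stats(config$pqtl_exposure)
      py <- read_summary_stats(config$pqtl_outcome)
      hp <- harmonise(px, py,
                      ld_matrix(diag(nrow(px)), rsids = px$rsid,
                                ref_alleles = px$effect_allele))
      results$pqtl <- scale_estimate(
        mr_ivw_uncorrelated(hp, analysis_id = "pqtl"), scale_mmhg)
      write_results(list(results$pqtl), file.path(out_dir, "pqtl.tsv"))
    }
    if ("stratified" %in% analyses) {
      stage <- "stratified"
      if (is.null(cohort)) stop("stratified requires a cohort input")
      results$stratified <- stratified_mr(cohort, exposure, ld,
                                          scale_mmhg)
      write_results(list(results$stratified$female,
                         results$stratified$male),
                    file.path(out_dir, "stratified.tsv"))
      .log_line(log_con, stage, sprintf(
        "female OR %.4f, male OR %.4f",
        results$stratified$female$scaled_or,
        results$stratified$male$scaled_or))
    }
  }, error = function(e) {
    .log_line(log_con, stage, paste("ERROR:", conditionMessage(e)))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  # forest-plot-ready combined table across analyses
  flat <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    if (inherits(r, "mr_estimate")) flat[[nm]] <- r
    else flat <- c(flat, Filter(function(z) inherits(z, "mr_estimate"), r))
  }
  write_results(unname(flat), file.path(out_dir, "forest.tsv"))

  manifest <- list(
    package = "cismr",
    version = as.character(utils::packageVersion("cismr")),
    seed = seed, scale_mmhg = scale_mmhg, analyses = analyses,
    config_hash = hash,
    n_instruments = length(h$rsids)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(results)
}
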
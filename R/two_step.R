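#' Mediator-on-outcome effect
#'
#' The external estimate of the mediating trait's effect on the outcome
#' (log-odds per mediator unit), e.g. BMI on Alzheimer's disease, supplied
#' to the two-step cis-MR adjustment rather than estimated internally.
#'
#' @param beta_co mediator-to-outcome effect, log-odds per mediator unit.
#' @param se_co its standard error, non-negative.
#' @return object of class `mediator_effect`.
#' @export
mediator_effect <- function(beta_co, se_co) {
  stopifnot(is.numeric(beta_co), is.numeric(se_co), se_co >= 0)
  structure(list(beta_co = as.numeric(beta_co), se_co = as.numeric(se_co)),
            class = "mediator_effect")
}

#' Adjust variant-outcome associations for a mediated path
#'
#' Subtracts the variant -> mediator -> outcome path from each
#' variant-outcome association, with first-order error propagation under
#' the two-sample independence assumption:
#'
#'   by_adj = by - bc * beta_co
#'   sy_adj = sqrt(sy^2 + bc^2 * se_co^2 + beta_co^2 * sc^2)
#'
#' so the adjusted SE is never smaller than the unadjusted one.
#'
#' @param by,sy variant-outcome log-odds and standard errors (vectorised).
#' @param bc,sc variant-mediator betas and standard errors.
#' @param med a [mediator_effect()].
#' @return list with `by_adj` and `sy_adj`.
#' @export
adjust_variant_outcome <- function(by, sy, bc, sc, med) {
  stopifnot(inherits(med, "mediator_effect"))
  if (any(c(sy, sc) < 0, na.rm = TRUE)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  list(
    by_adj = by - bc * med$beta_co,
    sy_adj = sqrt(sy^2 + bc^2 * med$se_co^2 + med$beta_co^2 * sc^2)
  )
}

#' Two-step cis-MR: IVW after mediation adjustment
#'
#' Applies [adjust_variant_outcome()] per instrument using the harmonised
#' variant-mediator betas, then re-runs the correlated IVW on the adjusted
#' outcome associations. A horizontal-pleiotropy sensitivity analysis: if
#' the instruments act on the outcome through the mediator (e.g. BMI), the
#' adjusted estimate removes that path.
#'
#' @param h a `harmonised_set` carrying mediator betas (`bc`, `sc`) for
#'   every instrument.
#' @param med a [mediator_effect()].
#' @return an `mr_estimate` with `analysis_id = "two_step_cis"`.
#' @export
two_step_mr <- function(h, med) {
  stopifnot(inherits(h, "harmonised_set"))
  if (is.null(h$bc) || is.null(h$sc)) {
    stop("harmonised set carries no mediator associations", call. = FALSE)
  }
  bad <- is.na(h$bc) | is.na(h$sc)
  if (any(bad)) {
    stop("missing mediator beta for instrument(s): ",
         paste(h$rsids[bad], collapse = ", "), call. = FALSE)
  }
  adj <- adjust_variant_outcome(h$by, h$sy, h$bc, h$sc, med)
  h_adj <- h
  h_adj$by <- adj$by_adj
  h_adj$sy <- adj$sy_adj
  mr_ivw_correlated(h_adj, analysis_id = "two_step_cis")
}
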
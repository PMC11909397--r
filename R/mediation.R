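# Two-step mediation over three univariable MR fits with the product method.

#' Proportion mediated by the product method on the log-odds scale
#'
#' `indirect = beta_em * beta_mo`, `proportion = indirect / beta_total`.
#' Additivity holds on the log scale, so ORs are converted with `log()`
#' upstream, never multiplied directly.
#'
#' @param beta_em Exposure -> mediator effect (log scale).
#' @param beta_mo Mediator -> outcome effect (log scale).
#' @param beta_total Total exposure -> outcome effect (log scale), nonzero.
#' @return List with `beta_indirect` and `proportion_mediated`.
#' @export
proportion_mediated <- function(beta_em, beta_mo, beta_total) {
  if (beta_total == 0) stop("beta_total = 0: proportion mediated is undefined")
  indirect <- beta_em * beta_mo
  list(beta_indirect = indirect, proportion_mediated = indirect / beta_total)
}

#' Two-step mediation analysis from four univariable MR fits
#'
#' The two-step design requires four conditions, evaluated at level `alpha`:
#' (1) forward exposure -> outcome association, (2) forward mediator ->
#' outcome association, (3) forward exposure -> mediator association, and
#' (4) NO reverse outcome -> exposure association (`pval > alpha`).  The
#' indirect effect is the product of the exposure->mediator and mediator->
#' outcome point estimates; the proportion mediated divides it by the total
#' effect.  Proportions above 1 are possible with inconsistent mediation and
#' flagged with a warning, not an error.
#'
#' @param mr_xy Total exposure -> outcome `mr_result`.
#' @param mr_xm Exposure -> mediator `mr_result`.
#' @param mr_my Mediator -> outcome `mr_result` (univariable; a
#'   mediator-adjusted direct-effect fit may be substituted via `mr_xy_direct`).
#' @param mr_reverse_yx Reverse outcome -> exposure `mr_result`.
#' @param alpha Significance level for the four conditions, default 0.05.
#' @param mr_xy_direct Optional direct-effect fit of exposure on outcome
#'   controlling for the mediator; when supplied it is reported alongside but
#'   the proportion still uses the univariable components (the default
#'   product-method definition).
#' @return Object of class `mediation_result`: the three betas,
#'   `beta_indirect`, `proportion_mediated` (fraction) and
#'   `proportion_mediated_pct`, the four condition booleans and their
#'   conjunction `valid`.
#' @export
two_step_mediation <- function(mr_xy, mr_xm, mr_my, mr_reverse_yx,
                               alpha = 0.05, mr_xy_direct = NULL) {
  conditions <- c(
    forward_exposure_outcome = mr_xy$pval <= alpha,
    forward_mediator_outcome = mr_my$pval <= alpha,
    forward_exposure_mediator = mr_xm$pval <= alpha,
    no_reverse_outcome_exposure = mr_reverse_yx$pval > alpha
  )
  beta_total <- mr_xy$beta_hat
  beta_em <- mr_xm$beta_hat
  beta_mo <- mr_my$beta_hat
  indirect <- beta_em * beta_mo
  if (beta_total == 0) {
    warning("total effect is zero; proportion mediated undefined")
    prop <- NA_real_
  } else {
    prop <- indirect / beta_total
    if (is.finite(prop) && abs(prop) > 1) {
      warning("indirect effect exceeds total effect (inconsistent mediation)")
    }
  }
  structure(list(
    beta_total = beta_total, beta_em = beta_em, beta_mo = beta_mo,
    beta_indirect = indirect,
    proportion_mediated = prop,
    proportion_mediated_pct = 100 * prop,
    conditions = conditions,
    valid = all(conditions),
    beta_direct = if (is.null(mr_xy_direct)) NA_real_ else mr_xy_direct$beta_hat,
    alpha = alpha
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: indirect = %.4f, total = %.4f, proportion = %.1f%% (valid: %s)\n",
              x$beta_indirect, x$beta_total, x$proportion_mediated_pct, x$valid))
  invisible(x)
}

#' Write a one-row mediation summary table
#' @param med A `mediation_result`.
#' @param exposure,mediator,outcome Trait labels for the row.
#' @param path Output TSV path.
#' @export
write_mediation <- function(med, exposure, mediator, outcome, path) {
  row <- data.frame(
    exposure = exposure, mediator = mediator, outcome = outcome,
    beta_total = med$beta_total, beta_em = med$beta_em, beta_mo = med$beta_mo,
    beta_indirect = med$beta_indirect,
    proportion_mediated = med$proportion_mediated,
    proportion_mediated_pct = med$proportion_mediated_pct,
    as.data.frame(as.list(med$conditions)),
    valid = med$valid
  )
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
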
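# Two-step mediation MR (protein -> mediator -> outcome) and sex-stratified
# effect comparison.

#' Two-step mediation MR
#'
#' Decomposes a protein's effect on the outcome through a mediator using the
#' coefficient-product method: the indirect effect is
#' `beta_step1 * beta_step2`, with first-order delta-method standard error
#' `sqrt(beta_step1^2 se_step2^2 + beta_step2^2 se_step1^2)` (no covariance
#' term: the two steps come from non-overlapping two-sample regressions).
#' The proportion mediated is `indirect / beta_total` and is reported as-is,
#' with a flag, when it falls outside \[0, 1\] or the total is zero.
#'
#' @param step1 [mr_result()] for protein -> mediator.
#' @param step2 [mr_result()] for mediator -> outcome.
#' @param total [mr_result()] for protein -> outcome (total effect).
#' @return One-row data frame of class `mediation_result` with the step
#'   estimates, `indirect`, `se_indirect`, `ci_low`/`ci_high` (95%), `pval`,
#'   `proportion_mediated` and `proportion_flag`.
#' @export
two_step_mediation <- function(step1, step2, total) {
  a <- step1$beta; sa <- step1$se
  b <- step2$beta; sb <- step2$se
  tot <- total$beta
  indirect <- a * b
  se_ind <- sqrt(a^2 * sb^2 + b^2 * sa^2)
  pval <- if (is.na(se_ind) || se_ind == 0) NA_real_ else
    two_sided_p(indirect / se_ind)
  proportion <- if (is.na(tot) || tot == 0) NA_real_ else indirect / tot
  flag <- if (is.na(proportion)) "undefined_total" else
    if (proportion < 0 || proportion > 1) "outside_unit_interval" else "ok"
  out <- data.frame(
    protein_id = step1$exposure, mediator_id = step1$outcome,
    beta_step1 = a, se_step1 = sa, beta_step2 = b, se_step2 = sb,
    beta_total = tot, se_total = total$se,
    indirect = indirect, se_indirect = se_ind,
    ci_low = indirect - CI_Z * se_ind, ci_high = indirect + CI_Z * se_ind,
    pval = pval, proportion_mediated = proportion, proportion_flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mediation_result", "data.frame")
  out
}

#' Bilateral Z-test for a sex-stratified effect difference
#'
#' `z = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)` with a two-sided normal
#' p-value.
#'
#' @param beta_f,se_f Female-stratum estimate and standard error (> 0).
#' @param beta_m,se_m Male-stratum estimate and standard error (> 0).
#' @return One-row data frame of class `subgroup_comparison` with `beta_f,
#'   se_f, beta_m, se_m, z_stat, pval`.
#' @export
subgroup_z_test <- function(beta_f, se_f, beta_m, se_m) {
  if (is.na(se_f) || is.na(se_m) || se_f <= 0 || se_m <= 0) {
    stop("standard errors must be positive")
  }
  z <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  out <- data.frame(beta_f = beta_f, se_f = se_f, beta_m = beta_m,
                    se_m = se_m, z_stat = z, pval = two_sided_p(z))
  class(out) <- c("subgroup_comparison", "data.frame")
  out
}
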
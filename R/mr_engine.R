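# Causal-effect estimation from harmonized instrument pairs.
#
# Single-instrument proteins use the Wald ratio; proteins with two or more
# independent instruments use the fixed-effect inverse-variance-weighted
# (IVW) estimator, which equals weighted least squares of the outcome effects
# on the exposure effects through the origin. Family-wise error is controlled
# by Bonferroni correction; causal direction is checked with the Steiger test
# and by reverse MR with the trait roles exchanged.

#' Construct an MR result
#'
#' One-row data frame holding a causal estimate and its uncertainty. The 95%
#' confidence interval uses the normal multiplier 1.959964 and the p-value is
#' the two-sided normal tail of `beta/se`.
#'
#' @param exposure_id,outcome_id Trait identifiers.
#' @param method Estimator tag (`"wald_ratio"`, `"ivw"`, or `"none"` for an
#'   empty result).
#' @param beta,se Causal estimate (SD outcome per SD exposure) and its
#'   standard error.
#' @param n_snp Number of instruments used.
#' @param steiger_pval,direction_ok Optional Steiger directionality results.
#' @return Data frame of class `mr_result` with columns `exposure, outcome,
#'   method, n_snp, beta, se, ci_low, ci_high, pval, steiger_pval,
#'   direction_ok`.
#' @export
mr_result <- function(exposure_id, outcome_id, method, beta = NA_real_,
                      se = NA_real_, n_snp = 0L, steiger_pval = NA_real_,
                      direction_ok = NA) {
  pval <- if (is.na(beta) || is.na(se) || se <= 0) NA_real_ else
    two_sided_p(beta / se)
  out <- data.frame(
    exposure = exposure_id, outcome = outcome_id, method = method,
    n_snp = as.integer(n_snp), beta = beta, se = se,
    ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se, pval = pval,
    steiger_pval = steiger_pval, direction_ok = direction_ok,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_result", "data.frame")
  out
}

# Accept either a harmonized-pairs row or a bare list with the named fields.
pair_fields <- function(pair) {
  list(bx = pair$beta_exp, sx = pair$se_exp, by = pair$beta_out,
       sy = pair$se_out)
}

#' Wald-ratio estimate from a single instrument
#'
#' `beta = beta_GY / beta_GX`. The default standard error is the first-order
#' delta approximation `SE_GY / |beta_GX|`; `second_order = TRUE` adds the
#' exposure-uncertainty term
#' `sqrt(SE_GY^2/beta_GX^2 + beta_GY^2 SE_GX^2 / beta_GX^4)`.
#'
#' @param pair One harmonized pair (row of [harmonize()] output or list with
#'   `beta_exp, se_exp, beta_out, se_out`).
#' @param second_order Use the second-order delta SE. Default `FALSE`.
#' @param exposure_id,outcome_id Trait labels for the result.
#' @return An [mr_result()].
#' @export
wald_ratio <- function(pair, second_order = FALSE, exposure_id = "exposure",
                       outcome_id = "outcome") {
  p <- pair_fields(pair)
  if (length(p$bx) != 1) stop("wald_ratio expects exactly one pair")
  if (p$bx == 0) stop("undefined Wald ratio: exposure beta is zero")
  beta <- p$by / p$bx
  se <- if (second_order) {
    sqrt(p$sy^2 / p$bx^2 + p$by^2 * p$sx^2 / p$bx^4)
  } else {
    p$sy / abs(p$bx)
  }
  mr_result(exposure_id, outcome_id, "wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Fixed-effect IVW with weights `w_j = 1/SE_GY_j^2`:
#' `beta = sum(w b_X b_Y) / sum(w b_X^2)`, `se = sqrt(1 / sum(w b_X^2))`.
#' With `random_effects = TRUE` the standard error is scaled by
#' `max(1, residual SD)` of the weighted through-origin regression
#' (multiplicative random effects).
#'
#' @param pairs Two or more harmonized pairs.
#' @param random_effects Apply the multiplicative random-effects scaling.
#' @param allow_single Permit a single pair (used internally by the
#'   dispatcher; the single-pair IVW equals the Wald ratio exactly).
#' @param exposure_id,outcome_id Trait labels for the result.
#' @return An [mr_result()].
#' @export
ivw <- function(pairs, random_effects = FALSE, allow_single = FALSE,
                exposure_id = "exposure", outcome_id = "outcome") {
  p <- pair_fields(pairs)
  k <- length(p$bx)
  if (k < 2 && !allow_single) {
    stop("IVW requires at least two instruments; use wald_ratio for one")
  }
  if (k < 1) stop("IVW requires at least one instrument")
  w <- 1 / p$sy^2
  denom <- sum(w * p$bx^2)
  beta <- sum(w * p$bx * p$by) / denom
  se <- sqrt(1 / denom)
  if (random_effects && k > 1) {
    resid <- p$by - beta * p$bx
    sigma2 <- sum(w * resid^2) / (k - 1)
    se <- se * sqrt(max(1, sigma2))
  }
  mr_result(exposure_id, outcome_id, "ivw", beta, se, k)
}

#' Fit the per-protein MR estimate
#'
#' Dispatch rule: zero pairs give an empty result (method `"none"`), one pair
#' the Wald ratio, two or more the IVW estimator.
#'
#' @param pairs Harmonized pairs (possibly zero rows).
#' @inheritParams ivw
#' @inheritParams wald_ratio
#' @return An [mr_result()].
#' @export
mr_fit <- function(pairs, random_effects = FALSE, second_order = FALSE,
                   exposure_id = "exposure", outcome_id = "outcome") {
  k <- length(pairs$beta_exp)
  if (k == 0) {
    mr_result(exposure_id, outcome_id, "none")
  } else if (k == 1) {
    wald_ratio(pairs, second_order = second_order,
               exposure_id = exposure_id, outcome_id = outcome_id)
  } else {
    ivw(pairs, random_effects = random_effects, exposure_id = exposure_id,
        outcome_id = outcome_id)
  }
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1\].
#' @param m_tests Number of tests (>= 1).
#' @return `alpha / m_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 1869)  # 2.675e-5
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  if (length(m_tests) != 1 || m_tests < 1) {
    stop("m_tests must be a single count >= 1")
  }
  stopifnot(alpha > 0, alpha <= 1)
  alpha / m_tests
}

#' Steiger directionality test for one instrument
#'
#' Compares the variance the instrument explains in the exposure versus the
#' outcome. With `r_X^2` and `r_Y^2` from [compute_pve()] on each side, the
#' causal direction is supported when `r_X^2 > r_Y^2`, with p-value from the
#' Fisher-z statistic
#' `z = (atanh|r_X| - atanh|r_Y|) / sqrt(1/(n_X - 3) + 1/(n_Y - 3))`
#' (two-sided normal tail).
#'
#' @param pair One harmonized pair carrying `n_exp` and `n_out` (> 3).
#' @return List with `direction_ok`, `pval`, `z`, `r2_exposure`,
#'   `r2_outcome`.
#' @export
steiger_test <- function(pair) {
  if (is.na(pair$n_exp) || is.na(pair$n_out) || pair$n_exp <= 3 ||
      pair$n_out <= 3) {
    stop("Steiger test requires n > 3 on both sides")
  }
  r2x <- compute_pve(pair$beta_exp, pair$se_exp, pair$eaf_exp, pair$n_exp)
  r2y <- compute_pve(pair$beta_out, pair$se_out, pair$eaf_out, pair$n_out)
  steiger_z(r2x, r2y, pair$n_exp, pair$n_out)
}

# Shared Fisher-z machinery for one or several instruments.
steiger_z <- function(r2x, r2y, nx, ny) {
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  list(direction_ok = r2x > r2y, pval = two_sided_p(z), z = z,
       r2_exposure = r2x, r2_outcome = r2y)
}

#' Steiger directionality for an instrument set
#'
#' Aggregates over instruments by summing the per-SNP variance explained on
#' each side (clipped at 1), then applies the same Fisher-z comparison with
#' the median sample size per side.
#'
#' @param pairs Harmonized pairs of the retained instruments.
#' @return As [steiger_test()].
#' @export
steiger_directionality <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(list(direction_ok = NA, pval = NA_real_, z = NA_real_,
                r2_exposure = NA_real_, r2_outcome = NA_real_))
  }
  r2x <- min(sum(compute_pve(pairs$beta_exp, pairs$se_exp, pairs$eaf_exp,
                             pairs$n_exp)), 1)
  r2y <- min(sum(compute_pve(pairs$beta_out, pairs$se_out, pairs$eaf_out,
                             pairs$n_out)), 1)
  steiger_z(r2x, r2y, stats::median(pairs$n_exp),
            stats::median(pairs$n_out))
}

#' Reverse MR with the trait roles exchanged
#'
#' Runs the identical selection and estimation machinery with the outcome
#' acting as exposure and the protein as outcome. When the outcome has no
#' genome-wide-significant instruments in the region, an empty result
#' (method `"none"`, zero SNPs) is returned.
#'
#' @param outcome_as_exposure `region_dataset` of the outcome trait (must
#'   carry gene coordinates and LD for the region; typically the same region
#'   object with the protein's coordinates).
#' @param protein_as_outcome `region_dataset` of the protein.
#' @param criteria An [instrument_criteria()].
#' @return An [mr_result()].
#' @export
reverse_mr <- function(outcome_as_exposure, protein_as_outcome,
                       criteria = instrument_criteria()) {
  iv <- select_instruments(outcome_as_exposure, protein_as_outcome, criteria)
  mr_fit(iv$pairs, exposure_id = outcome_as_exposure$trait_id,
         outcome_id = protein_as_outcome$trait_id)
}
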
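# Summary-data-based MR on the top cis-SNP, and the HEIDI test that
# distinguishes a single shared causal variant from linkage of distinct
# variants using the surrounding SNPs and their LD.

#' Summary-data-based MR (SMR) test
#'
#' Uses the top associated cis-SNP (smallest exposure p-value among SNPs
#' passing `qtl_pval_threshold` after harmonization; ties broken by SNP id).
#' With `z_X = beta_GX/SE_GX` and `z_Y = beta_GY/SE_GY`, the SMR statistic is
#' \deqn{T_{SMR} = \frac{z_X^2 z_Y^2}{z_X^2 + z_Y^2}}
#' referred to a chi-squared distribution with 1 df;
#' `beta_smr = beta_GY / beta_GX` and `se_smr = |beta_smr| / sqrt(T_SMR)`.
#'
#' @param region_exposure,region_outcome `region_dataset` objects for the
#'   protein and the outcome over the cis region.
#' @param qtl_pval_threshold Exposure significance threshold for eligible
#'   SNPs. Default `5e-8`.
#' @return Object of class `smr_result`: list with `protein_id`, `top_snp`,
#'   `beta_smr`, `se_smr`, `pval_smr`, `heidi_pval` (`NA` until
#'   [heidi_test()] is run), `n_heidi_snps`. When no SNP passes the
#'   threshold, an empty result (`top_snp = NA`) is returned.
#' @export
smr_test <- function(region_exposure, region_outcome,
                     qtl_pval_threshold = 5e-8) {
  h <- kept_pairs(harmonize(region_exposure, region_outcome))
  cand <- h[h$pval_exp < qtl_pval_threshold, , drop = FALSE]
  empty <- structure(
    list(protein_id = region_exposure$trait_id, top_snp = NA_character_,
         beta_smr = NA_real_, se_smr = NA_real_, pval_smr = NA_real_,
         heidi_pval = NA_real_, n_heidi_snps = 0L),
    class = "smr_result"
  )
  if (nrow(cand) == 0) return(empty)
  top <- cand[top_order(cand)[1], , drop = FALSE]
  zx <- top$beta_exp / top$se_exp
  zy <- top$beta_out / top$se_out
  t_smr <- if (zx == 0 && zy == 0) 0 else zx^2 * zy^2 / (zx^2 + zy^2)
  beta_smr <- top$beta_out / top$beta_exp
  se_smr <- if (t_smr > 0) abs(beta_smr) / sqrt(t_smr) else NA_real_
  structure(
    list(protein_id = region_exposure$trait_id, top_snp = top$snp,
         beta_smr = beta_smr, se_smr = se_smr,
         pval_smr = max(stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
                        P_FLOOR),
         heidi_pval = NA_real_, n_heidi_snps = 0L),
    class = "smr_result"
  )
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("<smr_result> %s top=%s beta=%.4g p=%.3g heidi=%.3g (%d SNPs)\n",
              x$protein_id, x$top_snp, x$beta_smr, x$pval_smr, x$heidi_pval,
              x$n_heidi_snps))
  invisible(x)
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Tests whether the SMR ratio is constant across SNPs in LD with the top
#' cis-SNP, as expected under a single shared causal variant; heterogeneity
#' indicates linkage of distinct causal variants. Candidate SNPs are the cis
#' SNPs with exposure `p < p_threshold` (excluding the top SNP) whose squared
#' correlation with the top SNP lies in `[r2_min, r2_max]`, capped at the
#' `max_snps` strongest. For each candidate, `d_i = beta_smr(i) -
#' beta_smr(top)`; the covariance of `d` follows from the delta method with
#' LD correlations among the SNP effects (exposure and outcome samples
#' independent). The statistic `Q = sum((d_i / SD(d_i))^2)` is referred to
#' the weighted chi-squared distribution with weights the eigenvalues of the
#' correlation matrix of the standardized `d` (Imhof numeric tail).
#'
#' @param region_exposure,region_outcome `region_dataset` objects.
#' @param ld Named LD correlation matrix covering the candidates, oriented to
#'   the exposure effect alleles.
#' @param p_threshold Exposure p-value ceiling for candidates. Default
#'   `1.57e-3`.
#' @param r2_min,r2_max Window of squared correlation with the top SNP.
#'   Defaults 0.05 and 0.9.
#' @param max_snps Cap on the number of candidates. Default 20.
#' @param qtl_pval_threshold Threshold defining the top SNP (as in
#'   [smr_test()]).
#' @return List with `heidi_pval` (`NA` when fewer than 3 usable candidates)
#'   and `n_snps_used`.
#' @export
heidi_test <- function(region_exposure, region_outcome, ld,
                       p_threshold = 1.57e-3, r2_min = 0.05, r2_max = 0.9,
                       max_snps = 20, qtl_pval_threshold = 5e-8) {
  h <- kept_pairs(harmonize(region_exposure, region_outcome))
  h <- h[h$snp %in% rownames(ld), , drop = FALSE]
  eligible <- h[h$pval_exp < qtl_pval_threshold, , drop = FALSE]
  if (nrow(eligible) == 0) {
    return(list(heidi_pval = NA_real_, n_snps_used = 0L))
  }
  top_id <- eligible$snp[top_order(eligible)[1]]

  r2_top <- ld[h$snp, top_id]^2
  cand <- h[h$snp != top_id & h$pval_exp < p_threshold &
              r2_top >= r2_min & r2_top <= r2_max, , drop = FALSE]
  cand <- cand[top_order(cand), , drop = FALSE]
  if (nrow(cand) > max_snps) cand <- cand[seq_len(max_snps), , drop = FALSE]
  if (nrow(cand) < 3) {
    return(list(heidi_pval = NA_real_, n_snps_used = nrow(cand)))
  }

  sel <- rbind(h[h$snp == top_id, , drop = FALSE], cand)
  m <- nrow(sel)
  bx <- sel$beta_exp; sx <- sel$se_exp
  by <- sel$beta_out; sy <- sel$se_out
  b <- by / bx
  r <- ld[sel$snp, sel$snp]

  # Delta-method covariance of the per-SNP ratios b_i = by_i / bx_i, with
  # cov(by_i, by_j) = r_ij sy_i sy_j and cov(bx_i, bx_j) = r_ij sx_i sx_j.
  cb <- r * outer(sy, sy) / outer(bx, bx) +
    outer(b, b) * r * outer(sx, sx) / outer(bx, bx)
  # Contrast against the top SNP (index 1): d_i = b_i - b_1.
  idx <- 2:m
  vd <- cb[idx, idx, drop = FALSE] -
    matrix(cb[idx, 1], m - 1, m - 1) -
    matrix(cb[1, idx], m - 1, m - 1, byrow = TRUE) + cb[1, 1]
  d <- b[idx] - b[1]
  sd_d <- sqrt(diag(vd))
  zd <- d / sd_d
  q <- sum(zd^2)
  corr_d <- vd / outer(sd_d, sd_d)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  list(heidi_pval = wchisq_tail(q, lambda), n_snps_used = m - 1L)
}

# Ranking of harmonized pairs by exposure association strength: ascending
# p, ties (the 1e-300 floor) broken by descending |z|, then id.
top_order <- function(h) {
  order(h$pval_exp, -abs(h$beta_exp / h$se_exp), h$snp)
}

# Tail probability P(sum_k lambda_k * chisq_1 > q) by Imhof's (1961)
# numeric inversion. The oscillatory integral is attempted at the requested
# tolerance first, then at progressively relaxed tolerances (quadrature
# roundoff limits the achievable precision for some weight spectra);
# Satterthwaite moment matching is the last resort.
wchisq_tail <- function(q, lambda, tol = 1e-8) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0 || q <= 0) return(1)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  for (tl in unique(pmax(c(tol, 1e-7, 1e-6, 1e-5), tol))) {
    res <- tryCatch(
      stats::integrate(integrand, 0, Inf, rel.tol = tl, abs.tol = tl,
                       subdivisions = 10000L),
      error = function(e) NULL
    )
    if (!is.null(res)) return(min(max(0.5 + res$value / pi, 0), 1))
  }
  scale <- sum(lambda^2) / sum(lambda)
  df <- sum(lambda)^2 / sum(lambda^2)
  stats::pchisq(q / scale, df = df, lower.tail = FALSE)
}
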
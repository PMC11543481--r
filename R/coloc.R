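# Approximate-Bayes-factor colocalization over a cis region.
#
# Five hypotheses are compared: H0 no causal variant for either trait; H1/H2
# one causal variant for one trait only; H3 two distinct causal variants; H4
# a single causal variant shared by both traits. Each SNP's evidence enters
# through a Wakefield approximate Bayes factor; all arithmetic is done in
# log space so that |z| far beyond 35 cannot overflow.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association and the prior standard
#' deviation of true effect sizes for a standardized quantitative trait.
#'
#' @param p1 Prior that a SNP is associated with the first trait. Default
#'   `1e-4`.
#' @param p2 Prior that a SNP is associated with the second trait. Default
#'   `1e-4`.
#' @param p12 Prior that a SNP is associated with both traits. Default
#'   `1e-5`.
#' @param prior_sd_a,prior_sd_b Prior effect-size SD for each trait. Default
#'   0.15 (standardized traits).
#' @return Object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_a = 0.15, prior_sd_b = 0.15) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1,
            prior_sd_a > 0, prior_sd_b > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, prior_sd_a = prior_sd_a,
                 prior_sd_b = prior_sd_b),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2` and `z = beta/se`:
#' \deqn{\log ABF = \tfrac12\left[\log\frac{V}{V+W} +
#'   z^2\frac{W}{V+W}\right]}
#' The log Bayes factor is even in `z`, so allele orientation does not affect
#' colocalization.
#'
#' @param beta,se Effect size and standard error (`se > 0`).
#' @param prior_sd Prior effect-size SD (> 0).
#' @return Log Bayes factor. Vectorized.
#' @export
wakefield_labf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("se must be positive")
  stopifnot(all(prior_sd > 0))
  v <- se^2
  w <- prior_sd^2
  z <- beta / se
  0.5 * (log(v / (v + w)) + z^2 * w / (v + w))
}

#' Approximate-Bayes-factor colocalization
#'
#' Computes the posterior probabilities of the five colocalization
#' hypotheses from the SNPs shared between two region datasets (intersected
#' by id and harmonized). With per-SNP Bayes factors `bf1_j`, `bf2_j` and
#' `S1 = sum(bf1)`, `S2 = sum(bf2)`, `S12 = sum(bf1*bf2)`, the unnormalized
#' hypothesis weights are `(1, p1*S1, p2*S2, p1*p2*(S1*S2 - S12),
#' p12*S12)`. Evidence tiers follow PP.H4: strong at `>= 0.80`, weak in
#' `[0.50, 0.80)`.
#'
#' @param region_a,region_b `region_dataset` objects for the two traits.
#' @param priors A [coloc_priors()] object.
#' @param palindrome_af_window Passed to [harmonize()].
#' @return Object of class `coloc_result`: list with `pp` (named
#'   `PP.H0 .. PP.H4`, summing to 1), `tier` (`"strong"`, `"weak"`,
#'   `"none"`), `n_snps`, and `snp_bf` (per-SNP log Bayes factors for
#'   regional diagnostics).
#' @export
coloc_abf <- function(region_a, region_b, priors = coloc_priors(),
                      palindrome_af_window = 0.08) {
  h <- kept_pairs(harmonize(region_a, region_b, palindrome_af_window))
  if (nrow(h) == 0) {
    stop("no shared SNPs between ", region_a$trait_id, " and ",
         region_b$trait_id, " after harmonization")
  }
  l1 <- wakefield_labf(h$beta_exp, h$se_exp, priors$prior_sd_a)
  l2 <- wakefield_labf(h$beta_out, h$se_out, priors$prior_sd_b)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lw <- c(
    PP.H0 = 0,
    PP.H1 = log(priors$p1) + ls1,
    PP.H2 = log(priors$p2) + ls2,
    PP.H3 = log(priors$p1) + log(priors$p2) + logdiffexp(ls1 + ls2, ls12),
    PP.H4 = log(priors$p12) + ls12
  )
  pp <- exp(lw - logsumexp(lw))
  tier <- if (pp[["PP.H4"]] >= 0.80) "strong" else
    if (pp[["PP.H4"]] >= 0.50) "weak" else "none"
  structure(
    list(pp = pp, tier = tier, n_snps = nrow(h),
         snp_bf = data.frame(snp = h$snp, labf_a = l1, labf_b = l2,
                             stringsAsFactors = FALSE)),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs, tier %s\n", x$n_snps, x$tier))
  print(round(x$pp, 4))
  invisible(x)
}
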
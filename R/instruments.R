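# Selection of valid cis instruments for a protein.
#
# A cis-pQTL is a valid instrument when it is genome-wide significant for the
# protein, lies within the cis window around the coding gene, falls outside
# the MHC region, survives allele harmonization with the outcome, is
# independent of stronger instruments after LD clumping, and has an
# F-statistic above the weak-instrument threshold.

#' Instrument-selection criteria
#'
#' Container for the thresholds applied by [select_instruments()].
#'
#' @param pval_threshold Genome-wide significance threshold for the
#'   protein association. Default `5e-8`.
#' @param clump_r2 Maximum squared LD correlation allowed between retained
#'   instruments. Default `0.001`.
#' @param cis_window_bp Window (base pairs) around the gene body defining a
#'   cis SNP. Default 1 Mb.
#' @param min_f_stat Minimum per-SNP F-statistic (exclusive). Default 10.
#' @param mhc_chrom,mhc_start_bp,mhc_end_bp Major histocompatibility complex
#'   region excluded for its complex LD (chr 6, 26-34 Mb by default).
#' @param palindrome_af_window Passed to [harmonize()].
#' @return Object of class `instrument_criteria`.
#' @export
instrument_criteria <- function(pval_threshold = 5e-8, clump_r2 = 0.001,
                                cis_window_bp = 1e6, min_f_stat = 10,
                                mhc_chrom = "6", mhc_start_bp = 26e6,
                                mhc_end_bp = 34e6,
                                palindrome_af_window = 0.08) {
  stopifnot(pval_threshold > 0, clump_r2 > 0, cis_window_bp > 0,
            min_f_stat > 0, mhc_start_bp < mhc_end_bp)
  structure(list(pval_threshold = pval_threshold, clump_r2 = clump_r2,
                 cis_window_bp = cis_window_bp, min_f_stat = min_f_stat,
                 mhc_chrom = as.character(mhc_chrom),
                 mhc_start_bp = mhc_start_bp, mhc_end_bp = mhc_end_bp,
                 palindrome_af_window = palindrome_af_window),
            class = "instrument_criteria")
}

#' Proportion of variance explained by a variant
#'
#' For a standardized trait, the variance explained by a single variant is
#' \deqn{R^2 = \frac{2f(1-f)\beta^2}{2f(1-f)\beta^2 + 2f(1-f)\,se^2 n}}
#' which reduces to \eqn{z^2 / (z^2 + n)} with \eqn{z = \beta/se}. The result
#' is clipped to \[0, 1\].
#'
#' @param beta,se Effect size and standard error (se > 0).
#' @param eaf Effect-allele frequency, strictly inside (0, 1); a monomorphic
#'   frequency of 0 or 1 is an error. `NA` is tolerated (the frequency term
#'   cancels algebraically).
#' @param n Sample size (> 1).
#' @return R-squared in \[0, 1\]. Vectorized.
#' @export
compute_pve <- function(beta, se, eaf, n) {
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    stop("monomorphic variant: eaf must lie strictly inside (0, 1)")
  }
  stopifnot(all(se > 0), all(n > 1))
  r2 <- beta^2 / (beta^2 + se^2 * n)
  pmin(pmax(r2, 0), 1)
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = \frac{n - 1 - k}{k}\cdot\frac{R^2}{1 - R^2}} for `k` instruments
#' jointly explaining `r2` of the exposure variance; `k = 1` for the per-SNP
#' statistic used in filtering.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Exposure sample size (`n > k + 1`).
#' @param k Number of instruments. Default 1.
#' @return F-statistic (>= 0). Vectorized.
#' @export
compute_f_stat <- function(r2, n, k = 1) {
  if (any(r2 >= 1)) stop("r2 must be < 1")
  stopifnot(all(r2 >= 0), all(n > k + 1), all(k >= 1))
  (n - 1 - k) / k * r2 / (1 - r2)
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by descending |z| when
#' supplied -- p-values at the 1e-300 floor are otherwise indistinguishable
#' -- then lexically by SNP id for determinism) and accepts each SNP iff its
#' squared correlation with every previously accepted SNP is below
#' `r2_threshold`. SNPs absent from the LD matrix are dropped with a message.
#'
#' @param snp_ids Character vector of candidate SNP ids.
#' @param pvals Their p-values (same order).
#' @param ld Named square LD correlation matrix covering the candidates.
#' @param r2_threshold Squared-correlation threshold (exclusive). Default
#'   0.001.
#' @param z Optional z statistics used to break p-value ties.
#' @return Character vector of retained SNP ids, in acceptance order.
#' @export
ld_clump <- function(snp_ids, pvals, ld, r2_threshold = 0.001, z = NULL) {
  stopifnot(length(snp_ids) == length(pvals))
  if (is.null(z)) z <- numeric(length(snp_ids))
  in_ld <- snp_ids %in% rownames(ld)
  if (any(!in_ld)) {
    message("ld_clump: dropping ", sum(!in_ld),
            " SNP(s) missing from the LD matrix: ",
            paste(snp_ids[!in_ld], collapse = ", "))
    pvals <- pvals[in_ld]
    z <- z[in_ld]
    snp_ids <- snp_ids[in_ld]
  }
  ord <- order(pvals, -abs(z), snp_ids)
  snp_ids <- snp_ids[ord]
  accepted <- character(0)
  for (s in snp_ids) {
    if (length(accepted) == 0 ||
        all(ld[s, accepted]^2 < r2_threshold)) {
      accepted <- c(accepted, s)
    }
  }
  accepted
}

#' Select cis instruments for a protein
#'
#' Applies, in order: genome-wide significance for the protein; the cis
#' filter (position overlapping `[gene_start - W, gene_end + W]` on the gene
#' chromosome, closed interval); MHC exclusion; allele harmonization with the
#' outcome; greedy LD clumping; and the F-statistic filter. Per-stage
#' attrition counts are recorded. An empty set is a valid result.
#'
#' @param protein `region_dataset` for the protein, with gene coordinates.
#' @param outcome `region_dataset` for the outcome trait.
#' @param criteria An [instrument_criteria()] object.
#' @return Object of class `instrument_set`: list with `protein_id`, `pairs`
#'   (harmonized pairs of the retained instruments, with `f_stat` and `pve`
#'   columns, sorted by p-value then id) and `attrition` (data frame of
#'   `stage`, `n_before`, `n_after`).
#' @export
select_instruments <- function(protein, outcome,
                               criteria = instrument_criteria()) {
  stopifnot(inherits(protein, "region_dataset"),
            inherits(outcome, "region_dataset"),
            inherits(criteria, "instrument_criteria"))
  if (is.na(protein$gene_start) || is.na(protein$gene_end) ||
      is.na(protein$gene_chrom)) {
    stop("protein region must carry gene coordinates for the cis filter")
  }
  stages <- character(0)
  n_before <- integer(0)
  n_after <- integer(0)
  note <- function(stage, before, after) {
    stages <<- c(stages, stage)
    n_before <<- c(n_before, before)
    n_after <<- c(n_after, after)
  }

  snps <- protein$snps
  n0 <- nrow(snps)

  keep <- snps$pval < criteria$pval_threshold
  note("pval", n0, sum(keep))
  snps <- snps[keep, , drop = FALSE]

  w <- criteria$cis_window_bp
  keep <- snps$chr == protein$gene_chrom &
    snps$pos >= protein$gene_start - w & snps$pos <= protein$gene_end + w
  note("cis", nrow(snps), sum(keep))
  snps <- snps[keep, , drop = FALSE]

  keep <- !(snps$chr == criteria$mhc_chrom &
              snps$pos >= criteria$mhc_start_bp &
              snps$pos <= criteria$mhc_end_bp)
  note("mhc", nrow(snps), sum(keep))
  snps <- snps[keep, , drop = FALSE]

  sub <- protein
  sub$snps <- snps
  sub$ld <- NULL
  pairs <- kept_pairs(harmonize(sub, outcome,
                                criteria$palindrome_af_window))
  note("harmonize", nrow(snps), nrow(pairs))

  if (nrow(pairs) > 1) {
    if (is.null(protein$ld)) {
      stop("LD matrix required to clump ", nrow(pairs), " candidates for ",
           protein$trait_id)
    }
    retained <- ld_clump(pairs$snp, pairs$pval_exp, protein$ld,
                         criteria$clump_r2,
                         z = pairs$beta_exp / pairs$se_exp)
  } else {
    retained <- pairs$snp
  }
  note("clump", nrow(pairs), length(retained))
  pairs <- pairs[pairs$snp %in% retained, , drop = FALSE]

  if (nrow(pairs) > 0) {
    pve <- instrument_pve(pairs)
    f <- compute_f_stat(pve, pairs$n_exp, k = 1)
    keep <- f > criteria$min_f_stat
    note("f_stat", nrow(pairs), sum(keep))
    pairs <- pairs[keep, , drop = FALSE]
    pairs$pve <- pve[keep]
    pairs$f_stat <- f[keep]
  } else {
    note("f_stat", 0L, 0L)
    pairs$pve <- numeric(0)
    pairs$f_stat <- numeric(0)
  }
  ord <- order(pairs$pval_exp, -abs(pairs$beta_exp / pairs$se_exp),
               pairs$snp)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL

  structure(
    list(protein_id = protein$trait_id, pairs = pairs,
         attrition = data.frame(stage = stages, n_before = n_before,
                                n_after = n_after,
                                stringsAsFactors = FALSE)),
    class = "instrument_set"
  )
}

# Exposure-side PVE for harmonized pairs; tolerates missing eaf (the
# frequency term cancels in the standardized-trait formula).
instrument_pve <- function(pairs) {
  compute_pve(pairs$beta_exp, pairs$se_exp,
              ifelse(is.na(pairs$eaf_exp), NA_real_, pairs$eaf_exp),
              pairs$n_exp)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instrument(s)\n", x$protein_id,
              nrow(x$pairs)))
  invisible(x)
}
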
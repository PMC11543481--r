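# Allele harmonization between an exposure and an outcome dataset.
#
# Two-sample MR requires the exposure and outcome effect sizes to refer to
# the same effect allele. Records are matched by SNP id; outcome alleles that
# are swapped relative to the exposure get their effect sign and frequency
# reflected; apparent strand flips of non-palindromic SNPs are resolved by
# complementing before declaring a pair incompatible. Palindromic (A/T, C/G)
# SNPs are aligned by allele frequency and dropped when the frequency is too
# close to 0.5 to resolve the strand.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) ALLELE_COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records to the exposure's effect allele, SNP by SNP. Each
#' shared SNP receives a status:
#' \describe{
#'   \item{kept}{Same orientation (possibly after complementing a strand
#'     flip); outcome left unchanged.}
#'   \item{flipped}{Alleles swapped relative to the exposure; outcome beta
#'     negated and frequency reflected (`eaf -> 1 - eaf`).}
#'   \item{dropped_palindromic}{A/T or C/G SNP whose minor-allele frequency is
#'     within `palindrome_af_window` of 0.5 on either side (or whose
#'     frequency is missing), so the strand cannot be resolved.}
#'   \item{dropped_incompatible}{Allele sets that cannot be reconciled.}
#' }
#' Palindromic SNPs clear of the ambiguity window are aligned by allele
#' frequency: when the exposure and (label-aligned) outcome frequencies fall
#' on opposite sides of 0.5 the outcome is assumed strand-flipped and the
#' alignment is toggled.
#'
#' @param exposure,outcome `region_dataset` objects keyed by SNP id.
#' @param palindrome_af_window Half-width of the frequency window around 0.5
#'   inside which palindromic SNPs are dropped; in \[0, 0.5). Default 0.08.
#' @return Data frame of class `harmonized_pairs` with one row per shared SNP
#'   (exposure orientation): `snp, chr, pos, ea, oa, eaf_exp, beta_exp,
#'   se_exp, pval_exp, n_exp, eaf_out, beta_out, se_out, pval_out, n_out,
#'   status`. Dropped SNPs are retained with their status; use
#'   [kept_pairs()] for the surviving rows.
#' @export
harmonize <- function(exposure, outcome, palindrome_af_window = 0.08) {
  stopifnot(inherits(exposure, "region_dataset"),
            inherits(outcome, "region_dataset"),
            palindrome_af_window >= 0, palindrome_af_window < 0.5)
  ex <- exposure$snps
  ou <- outcome$snps
  shared <- intersect(ex$snp, ou$snp)
  ex <- ex[match(shared, ex$snp), , drop = FALSE]
  ou <- ou[match(shared, ou$snp), , drop = FALSE]

  n <- length(shared)
  status <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  min_af <- 0.5 - palindrome_af_window

  for (i in seq_len(n)) {
    e_ea <- ex$ea[i]; e_oa <- ex$oa[i]
    o_ea <- ou$ea[i]; o_oa <- ou$oa[i]
    if (is_palindromic(e_ea, e_oa)) {
      if (!setequal(c(o_ea, o_oa), c(e_ea, e_oa))) {
        status[i] <- "dropped_incompatible"
        next
      }
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      ambiguous <- is.na(fe) || is.na(fo) ||
        pmin(fe, 1 - fe) > min_af || pmin(fo, 1 - fo) > min_af
      if (ambiguous) {
        status[i] <- "dropped_palindromic"
        next
      }
      # Tentative alignment by allele label, then strand check by frequency.
      flip <- o_ea != e_ea
      fo_aligned <- if (flip) 1 - fo else fo
      if ((fe < 0.5) != (fo_aligned < 0.5)) flip <- !flip
      status[i] <- if (flip) "flipped" else "kept"
      if (flip) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      }
    } else {
      # Direct match, swapped match, then the strand-complemented versions.
      c_ea <- ALLELE_COMPLEMENT[o_ea]; c_oa <- ALLELE_COMPLEMENT[o_oa]
      if (o_ea == e_ea && o_oa == e_oa) {
        status[i] <- "kept"
      } else if (o_ea == e_oa && o_oa == e_ea) {
        status[i] <- "flipped"
      } else if (c_ea == e_ea && c_oa == e_oa) {
        status[i] <- "kept"
      } else if (c_ea == e_oa && c_oa == e_ea) {
        status[i] <- "flipped"
      } else {
        status[i] <- "dropped_incompatible"
        next
      }
      if (status[i] == "flipped") {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      }
    }
  }

  out <- data.frame(
    snp = shared, chr = ex$chr, pos = ex$pos, ea = ex$ea, oa = ex$oa,
    eaf_exp = ex$eaf, beta_exp = ex$beta, se_exp = ex$se,
    pval_exp = ex$pval, n_exp = ex$n,
    eaf_out = eaf_out, beta_out = beta_out, se_out = ou$se,
    pval_out = ou$pval, n_out = ou$n,
    status = status, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' Surviving harmonized pairs
#'
#' @param pairs Result of [harmonize()].
#' @return The rows with status `kept` or `flipped`.
#' @export
kept_pairs <- function(pairs) {
  out <- pairs[pairs$status %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write harmonized pairs as TSV
#'
#' @param pairs Result of [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
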
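# Builders for small in-code fixtures.

make_snps <- function(n = 3, snp = sprintf("rs%02d", seq_len(n)),
                      chr = "1", pos = seq(1e6, by = 1000, length.out = n),
                      ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                      pval = NULL, n_gwas = 50000) {
  df <- data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
                   eaf = eaf, beta = beta, se = se, pval = NA_real_,
                   n = n_gwas, stringsAsFactors = FALSE)
  df$pval <- if (is.null(pval)) {
    pmax(2 * stats::pnorm(-abs(df$beta / df$se)), 1e-300)
  } else {
    pval
  }
  df
}

make_region <- function(df, trait_id = "prot", trait_kind = "protein",
                        gene_chrom = "1", gene_start = 1e6,
                        gene_end = 1.02e6, ld = NULL) {
  region_dataset(df, trait_id = trait_id, trait_kind = trait_kind,
                 gene_chrom = gene_chrom, gene_start = gene_start,
                 gene_end = gene_end, ld = ld)
}

# A pair of harmonizable regions with prescribed exposure/outcome effects.
make_pair_regions <- function(beta_exp, se_exp, beta_out, se_out,
                              eaf = 0.3, n_exp = 50000, n_out = 400000,
                              ld = NULL) {
  k <- length(beta_exp)
  ids <- sprintf("rs%02d", seq_len(k))
  exp_df <- make_snps(k, snp = ids, eaf = eaf, beta = beta_exp, se = se_exp,
                      n_gwas = n_exp)
  out_df <- make_snps(k, snp = ids, eaf = eaf, beta = beta_out, se = se_out,
                      n_gwas = n_out)
  list(exposure = make_region(exp_df, "prot", "protein", ld = ld),
       outcome = make_region(out_df, "out", "outcome"))
}
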
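# Data model and file I/O for GWAS summary statistics over a cis region.
#
# A region dataset holds one trait's marginal associations (one row per SNP)
# together with the coding-gene coordinates that anchor the cis window and,
# optionally, the LD correlation matrix among the SNPs.

#' Column mapping for summary-statistic tables
#'
#' Returns the named vector that maps the internal field names to the column
#' headers of a tab-separated summary-statistics file. Override individual
#' entries to read files with non-default headers.
#'
#' @param snp,chr,pos,ea,oa,eaf,beta,se,p,n Column headers for the SNP
#'   identifier, chromosome, base-pair position, effect allele, other allele,
#'   effect-allele frequency, effect size, standard error, p-value and sample
#'   size.
#' @return Named character vector with one entry per field.
#' @export
#' @examples
#' summary_columns(p = "pvalue")
summary_columns <- function(snp = "SNP", chr = "CHR", pos = "BP", ea = "EA",
                            oa = "OA", eaf = "EAF", beta = "BETA", se = "SE",
                            p = "P", n = "N") {
  c(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
    beta = beta, se = se, p = p, n = n)
}

VALID_ALLELES <- c("A", "C", "G", "T")

# Fields every record carries internally.
ASSOC_FIELDS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                  "pval", "n")

#' Validate variant-association records
#'
#' Applies the row-level invariants of a summary-statistics table: alleles are
#' single bases A/C/G/T and distinct, `se > 0`, `eaf` (when present) lies in
#' \[0, 1\], `pval` lies in (0, 1\] after flooring at `1e-300`, `n > 0`, SNP
#' ids are unique, and a reported p-value must agree with the two-sided normal
#' tail of `beta/se` (10% relative tolerance on the log scale, with a one-ULP
#' allowance for printed rounding). Missing p-values are filled from `beta/se`.
#'
#' @param snps Data frame with columns `snp, chr, pos, ea, oa, eaf, beta, se,
#'   pval, n`.
#' @return List with elements `keep` (the validated data frame) and `dropped`
#'   (data frame of `snp`, `reason` for every discarded row).
#' @export
validate_associations <- function(snps) {
  stopifnot(is.data.frame(snps))
  missing <- setdiff(ASSOC_FIELDS, names(snps))
  if (length(missing) > 0) {
    stop("missing required fields: ", paste(missing, collapse = ", "))
  }
  snps$snp <- as.character(snps$snp)
  snps$chr <- as.character(snps$chr)
  snps$ea <- toupper(as.character(snps$ea))
  snps$oa <- toupper(as.character(snps$oa))

  reason <- rep(NA_character_, nrow(snps))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }

  flag(!(snps$ea %in% VALID_ALLELES) | !(snps$oa %in% VALID_ALLELES) |
         snps$ea == snps$oa, "bad_allele")
  flag(is.na(snps$beta) | !is.finite(snps$beta), "bad_beta")
  flag(is.na(snps$se) | !is.finite(snps$se) | snps$se <= 0, "se_nonpos")
  flag(!is.na(snps$eaf) & (snps$eaf < 0 | snps$eaf > 1), "eaf_range")
  flag(!is.na(snps$n) & snps$n <= 0, "n_nonpos")

  # Fill missing p-values from the z statistic; floor tiny values.
  z <- snps$beta / snps$se
  p_implied <- two_sided_p(z)
  fill <- is.na(snps$pval) & is.na(reason)
  snps$pval[fill] <- p_implied[fill]
  flag(!is.na(snps$pval) & (snps$pval <= 0 | snps$pval > 1), "pval_range")
  snps$pval <- pmax(snps$pval, P_FLOOR)

  # Consistency between the reported p and |beta/se| (log scale).
  lp <- log(snps$pval)
  lpz <- log(p_implied)
  tol <- pmax(log(1.1), 0.1 * abs(lpz))
  flag(is.na(reason) & abs(lp - lpz) > tol, "pval_inconsistent")

  flag(duplicated(snps$snp), "duplicate_id")

  keep <- snps[is.na(reason), ASSOC_FIELDS, drop = FALSE]
  rownames(keep) <- NULL
  dropped <- data.frame(snp = snps$snp[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(keep = keep, dropped = dropped)
}

#' Construct a cis-region dataset
#'
#' Bundles one trait's variant associations with the coordinates of the gene
#' encoding the protein (used to anchor the cis window) and, optionally, the
#' LD correlation matrix for the region. Rows violating the record invariants
#' are dropped and counted (see [validate_associations()]).
#'
#' @param snps Data frame of variant associations (fields as in
#'   [validate_associations()]).
#' @param trait_id Trait identifier.
#' @param trait_kind One of `"protein"`, `"outcome"`, `"mediator"`.
#' @param gene_chrom,gene_start,gene_end Coding-gene coordinates (1-based,
#'   closed interval). May be `NA` for traits without a cis anchor.
#' @param ld Optional square LD correlation matrix whose row/column names all
#'   appear among the SNP ids.
#' @param validate Run row validation (default `TRUE`).
#' @return Object of class `region_dataset`: a list with elements `trait_id`,
#'   `trait_kind`, `gene_chrom`, `gene_start`, `gene_end`, `snps`, `ld`, and
#'   attributes `n_dropped` / `dropped` recording validation attrition.
#' @export
region_dataset <- function(snps, trait_id,
                           trait_kind = c("protein", "outcome", "mediator"),
                           gene_chrom = NA_character_, gene_start = NA_real_,
                           gene_end = NA_real_, ld = NULL, validate = TRUE) {
  trait_kind <- match.arg(trait_kind)
  dropped <- data.frame(snp = character(), reason = character())
  if (validate) {
    v <- validate_associations(snps)
    snps <- v$keep
    dropped <- v$dropped
  }
  if (anyDuplicated(snps$snp)) stop("snp ids must be unique")
  if (!is.null(ld)) {
    ids <- rownames(ld)
    if (is.null(ids) || !all(ids %in% snps$snp)) {
      stop("every LD row/column label must appear among the records")
    }
  }
  structure(
    list(trait_id = trait_id, trait_kind = trait_kind,
         gene_chrom = as.character(gene_chrom), gene_start = gene_start,
         gene_end = gene_end, snps = snps, ld = ld),
    n_dropped = nrow(dropped), dropped = dropped,
    class = "region_dataset"
  )
}

#' @export
print.region_dataset <- function(x, ...) {
  cat(sprintf("<region_dataset> %s (%s): %d SNPs%s\n", x$trait_id,
              x$trait_kind, nrow(x$snps),
              if (is.null(x$ld)) "" else sprintf(", LD %dx%d", nrow(x$ld),
                                                 ncol(x$ld))))
  invisible(x)
}

#' Read a summary-statistics table
#'
#' Reads a tab-separated file of GWAS summary statistics into a
#' [region_dataset()]. Rows failing the record invariants are dropped and
#' counted in the returned object's attributes; a missing required column or
#' an empty file is a fatal error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named vector from [summary_columns()] resolving the file's
#'   headers. `eaf`, `p` and `n` are optional columns; all others are required.
#' @inheritParams region_dataset
#' @return A `region_dataset`.
#' @export
read_summary_table <- function(path, column_map = summary_columns(),
                               trait_id = basename(path),
                               trait_kind = "protein",
                               gene_chrom = NA_character_,
                               gene_start = NA_real_, gene_end = NA_real_,
                               ld = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("empty summary-statistics file: ", path)
  required <- setdiff(ASSOC_FIELDS_EXTERNAL_REQUIRED, character())
  for (field in required) {
    if (!(column_map[[field]] %in% names(tab))) {
      stop("missing required column '", column_map[[field]], "' in ", path)
    }
  }
  get_col <- function(field, default = NA_real_) {
    col <- column_map[[field]]
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  snps <- data.frame(
    snp = as.character(get_col("snp")), chr = as.character(get_col("chr")),
    pos = as.numeric(get_col("pos")), ea = as.character(get_col("ea")),
    oa = as.character(get_col("oa")), eaf = as.numeric(get_col("eaf")),
    beta = as.numeric(get_col("beta")), se = as.numeric(get_col("se")),
    pval = as.numeric(get_col("p")), n = as.numeric(get_col("n")),
    stringsAsFactors = FALSE
  )
  region_dataset(snps, trait_id = trait_id, trait_kind = trait_kind,
                 gene_chrom = gene_chrom, gene_start = gene_start,
                 gene_end = gene_end, ld = ld)
}

# Columns that must be present in an input file (p, eaf, n may be absent).
ASSOC_FIELDS_EXTERNAL_REQUIRED <- c("snp", "chr", "pos", "ea", "oa", "beta",
                                    "se")

#' Write a summary-statistics table
#'
#' Inverse of [read_summary_table()]: writes the records of a region dataset
#' as a tab-separated file using the given column headers. Round-trips
#' preserve all fields to full printed precision.
#'
#' @param region A `region_dataset`.
#' @param path Output path.
#' @param column_map Named vector from [summary_columns()].
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(region, path,
                                column_map = summary_columns()) {
  out <- region$snps
  names(out) <- unname(column_map[c("snp", "chr", "pos", "ea", "oa", "eaf",
                                    "beta", "se", "p", "n")])
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD correlation matrix
#'
#' Reads a square tab-separated numeric table whose first column and header
#' row carry SNP ids, then repairs it: the matrix is symmetrized as
#' `(M + t(M))/2`, the diagonal is forced to 1, and negative eigenvalues are
#' floored at zero so the result is positive semi-definite.
#'
#' @param path Path to the tab-separated matrix.
#' @return A named square numeric matrix of pairwise correlations.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    stop("LD matrix must be square: ", nrow(m), " x ", ncol(m))
  }
  repair_ld(m, rownames(m))
}

# Symmetrize, force unit diagonal, floor eigenvalues at zero. After
# flooring, the matrix is renormalized to unit diagonal as a correlation
# (D^{-1/2} M D^{-1/2}), which preserves positive semi-definiteness.
repair_ld <- function(m, snp_ids) {
  storage.mode(m) <- "double"
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    m <- (m + t(m)) / 2
    d <- sqrt(pmax(diag(m), .Machine$double.eps))
    m <- m / outer(d, d)
    diag(m) <- 1
  }
  m[m > 1] <- 1
  m[m < -1] <- -1
  dimnames(m) <- list(snp_ids, snp_ids)
  m
}

#' Write an LD correlation matrix
#'
#' @param ld Named square numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(format(ld, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
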
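# Summary-statistic I/O, record validation, LD repair, harmonization.

test_that("a well-formed table reads, and write/read round-trips all fields", {
  df <- make_snps(3, eaf = c(0.1, 0.25, NA), beta = c(0.1, -0.05, 0.2),
                  se = c(0.02, 0.01, 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(make_region(df), path)
  region <- read_summary_table(path, trait_id = "prot", trait_kind = "protein",
                               gene_chrom = "1", gene_start = 1e6,
                               gene_end = 1.02e6)
  expect_s3_class(region, "region_dataset")
  expect_equal(nrow(region$snps), 3)
  expect_equal(attr(region, "n_dropped"), 0)

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(region, path2)
  rt <- read_summary_table(path2, trait_id = "prot")
  expect_equal(rt$snps, region$snps, tolerance = 1e-12)
})

test_that("rows violating record invariants are dropped and counted", {
  df <- rbind(
    make_snps(2),
    transform(make_snps(1, snp = "bad_se"), se = 0),
    transform(make_snps(1, snp = "bad_eaf"), eaf = 1.5),
    transform(make_snps(1, snp = "bad_p"), pval = 0.9),   # z ~ 5, p must be tiny
    transform(make_snps(1, snp = "rs01"), pos = 2e6)      # duplicate id
  )
  v <- validate_associations(df)
  expect_equal(nrow(v$keep), 2)
  expect_setequal(v$dropped$reason,
                  c("se_nonpos", "eaf_range", "pval_inconsistent",
                    "duplicate_id"))

  region <- make_region(df)
  expect_equal(attr(region, "n_dropped"), 4)
})

test_that("p-values are floored and filled from beta/se when missing", {
  df <- make_snps(2, beta = c(1, 0.1), se = c(0.01, 0.05),
                  pval = c(1e-320, NA))
  v <- validate_associations(df)
  expect_equal(v$keep$pval[1], 1e-300)
  expect_equal(v$keep$pval[2], 2 * pnorm(-2))
})

test_that("missing required columns and empty files are fatal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- make_snps(2)
  write_summary_table(make_region(df), path)
  tab <- read.delim(path)
  writeLines(paste(names(tab)[-1], collapse = "\t"), path)  # header only
  expect_error(read_summary_table(path), "empty")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, setdiff(names(tab), "SE")], path2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_summary_table(path2), "missing required column 'SE'")
})

test_that("LD matrices are symmetrized, unit-diagonal and PSD-repaired", {
  ids <- c("a", "b", "c")
  path <- withr::local_tempfile(fileext = ".tsv")

  eye <- diag(3)
  dimnames(eye) <- list(ids, ids)
  write_ld_matrix(eye, path)
  expect_equal(unname(read_ld_matrix(path)), diag(3))

  m <- diag(3)
  m[1, 2] <- 0.5
  m[2, 1] <- 0.48
  dimnames(m) <- list(ids, ids)
  write_ld_matrix(m, path)
  r <- read_ld_matrix(path)
  expect_equal(r[1, 2], 0.49)
  expect_equal(r[2, 1], 0.49)

  # Indefinite input: eigenvalues floored at zero, diagonal restored.
  bad <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 1), 3,
                dimnames = list(ids, ids))
  write_ld_matrix(bad, path)
  fixed <- read_ld_matrix(path)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-8)
  expect_equal(unname(diag(fixed)), rep(1, 3))

  # AR(1) input is already PSD and must come back unchanged.
  ar <- make_ld(5, 0.8)
  write_ld_matrix(ar, path)
  expect_equal(read_ld_matrix(path), ar, tolerance = 1e-12)
  expect_gte(min(eigen(read_ld_matrix(path))$values), 0)

  writeLines(c("\tx\ty", "x\t1\t0"), path)
  expect_error(read_ld_matrix(path), "square")
})

test_that("harmonization assigns the documented statuses", {
  cases <- list(
    # exposure EA/OA, outcome EA/OA, outcome eaf, expected status,
    # expected beta factor (NA = dropped)
    list(c("A", "G"), c("A", "G"), 0.3, "kept", 1),
    list(c("A", "G"), c("G", "A"), 0.3, "flipped", -1),
    list(c("A", "G"), c("T", "C"), 0.3, "kept", 1),        # strand flip
    list(c("A", "G"), c("C", "T"), 0.3, "flipped", -1),    # strand + swap
    list(c("A", "G"), c("A", "C"), 0.3, "dropped_incompatible", NA),
    list(c("A", "T"), c("A", "T"), 0.50, "dropped_palindromic", NA),
    list(c("A", "T"), c("A", "T"), 0.20, "kept", 1),
    list(c("A", "T"), c("A", "T"), 0.80, "flipped", -1),   # strand-flipped
    list(c("C", "G"), c("G", "C"), 0.75, "flipped", -1),
    list(c("A", "T"), c("A", "T"), NA, "dropped_palindromic", NA)
  )
  for (cs in cases) {
    exp_df <- make_snps(1, ea = cs[[1]][1], oa = cs[[1]][2], eaf = 0.2,
                        beta = 0.1)
    out_df <- make_snps(1, ea = cs[[2]][1], oa = cs[[2]][2], eaf = cs[[3]],
                        beta = 0.05)
    h <- harmonize(make_region(exp_df), make_region(out_df, "out", "outcome"),
                   palindrome_af_window = 0.08)
    expect_equal(h$status, cs[[4]],
                 label = paste(unlist(cs[1:3]), collapse = "/"))
    if (!is.na(cs[[5]])) {
      expect_equal(h$beta_out, cs[[5]] * 0.05)
      if (cs[[4]] == "flipped") expect_equal(h$eaf_out, 1 - cs[[3]])
    }
  }
})

test_that("palindromic ambiguity window boundary is honoured", {
  exp_df <- make_snps(1, ea = "A", oa = "T", eaf = 0.42, beta = 0.1)
  out_df <- make_snps(1, ea = "A", oa = "T", eaf = 0.42, beta = 0.05)
  h <- harmonize(make_region(exp_df), make_region(out_df, "out", "outcome"),
                 palindrome_af_window = 0.08)
  expect_equal(h$status, "kept")  # min(eaf, 1-eaf) == 0.42, not > 0.42
  out_df$eaf <- exp_df$eaf <- 0.43
  h <- harmonize(make_region(exp_df), make_region(out_df, "out", "outcome"),
                 palindrome_af_window = 0.08)
  expect_equal(h$status, "dropped_palindromic")
})

test_that("pre-swapping exposure alleles leaves effect products invariant", {
  set.seed(41)
  n <- 12
  ea <- sample(c("A", "C", "G"), n, replace = TRUE)
  oa <- ifelse(ea == "A", "G", "T")
  exp_df <- make_snps(n, ea = ea, oa = oa, eaf = runif(n, 0.05, 0.45),
                      beta = rnorm(n, 0, 0.2), se = 0.02)
  out_df <- make_snps(n, ea = ea, oa = oa, eaf = exp_df$eaf,
                      beta = rnorm(n, 0, 0.05), se = 0.01)
  h1 <- kept_pairs(harmonize(make_region(exp_df),
                             make_region(out_df, "out", "outcome")))
  swapped <- transform(exp_df, ea = oa, oa = ea, beta = -beta,
                       eaf = 1 - eaf)
  h2 <- kept_pairs(harmonize(make_region(swapped),
                             make_region(out_df, "out", "outcome")))
  expect_equal(h1$beta_exp * h1$beta_out, h2$beta_exp * h2$beta_out)
})
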
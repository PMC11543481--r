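# Instrument strength statistics, LD clumping, and the five-criterion
# selection of cis instruments.

test_that("compute_pve matches the standardized-trait formula", {
  expect_equal(compute_pve(0, 0.02, 0.3, 5e4), 0)
  # z = 0.1/0.004472 ~ 22.36, R2 ~ z^2/(z^2+n)
  expect_equal(compute_pve(0.1, 0.004472, 0.3, 5e4), 0.00990, tolerance = 1e-3)
  # symmetric in eaf
  expect_equal(compute_pve(0.12, 0.01, 0.2, 1e4),
               compute_pve(0.12, 0.01, 0.8, 1e4))
  # frequency term cancels entirely
  expect_equal(compute_pve(0.12, 0.01, 0.2, 1e4),
               compute_pve(0.12, 0.01, 0.45, 1e4))
  expect_error(compute_pve(0.1, 0.02, 0, 5e4), "monomorphic")
  expect_error(compute_pve(0.1, 0.02, 1, 5e4), "monomorphic")
})

test_that("compute_f_stat matches its closed form and is monotone in r2", {
  expect_equal(compute_f_stat(0, 5e4), 0)
  expect_equal(compute_f_stat(0.0042, 5e4, 1), 210.9, tolerance = 1e-3)
  r2 <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(compute_f_stat(r2, 1e4)) > 0))
  expect_error(compute_f_stat(1, 5e4), "r2")
})

test_that("ld_clump keeps independent SNPs and prefers smaller p in LD", {
  ids <- paste0("s", 1:3)
  eye <- diag(3)
  dimnames(eye) <- list(ids, ids)
  expect_setequal(ld_clump(ids, c(1e-8, 1e-9, 1e-10), eye), ids)

  r <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2,
              dimnames = list(ids[1:2], ids[1:2]))
  expect_equal(ld_clump(ids[1:2], c(1e-8, 1e-10), r), "s2")

  expect_message(
    kept <- ld_clump(c(ids, "absent"), c(1e-8, 1e-9, 1e-10, 1e-12), eye),
    "missing from the LD matrix")
  expect_setequal(kept, ids)
})

test_that("greedy clumping equals the brute-force p-ranked maximal set", {
  # Oracle: enumerate all subsets; valid = pairwise r2 below threshold;
  # among maximal valid subsets pick the one whose sorted p-ranks are
  # lexicographically smallest (i.e. always take the best available SNP).
  clump_oracle <- function(ids, pvals, ld, thr) {
    k <- length(ids)
    rank_of <- order(order(pvals, ids))
    valid <- function(sub) {
      if (length(sub) < 2) return(TRUE)
      r2 <- ld[sub, sub]^2
      all(r2[upper.tri(r2)] < thr)
    }
    subsets <- lapply(seq_len(2^k) - 1,
                      function(m) ids[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
    valids <- Filter(valid, subsets)
    maximal <- Filter(function(s) {
      !any(vapply(setdiff(ids, s),
                  function(x) valid(c(s, x)), logical(1)))
    }, valids)
    keys <- vapply(maximal, function(s) {
      paste(sprintf("%02d", sort(rank_of[match(s, ids)])), collapse = "")
    }, character(1))
    maximal[[order(keys)[1]]]
  }

  ids <- paste0("s", 1:5)
  ld <- make_ld(5, 0.9, ids)
  pv <- c(1e-12, 1e-9, 1e-7, 1e-6, 1e-5)
  for (thr in c(0.001, 0.5, 0.7)) {
    got <- ld_clump(ids, pv, ld, thr)
    want <- clump_oracle(ids, pv, ld, thr)
    expect_setequal(got, want)
    # validity of the greedy output
    if (length(got) > 1) {
      r2 <- ld[got, got]^2
      expect_true(all(r2[upper.tri(r2)] < thr))
    }
  }
})

test_that("select_instruments applies all five criteria", {
  crit <- instrument_criteria()
  out_region <- function(df) make_region(df, "out", "outcome")

  good <- make_snps(1, beta = 0.1, se = 0.01)   # p ~ 1e-23, F ~ 100
  iv <- select_instruments(make_region(good), out_region(good), crit)
  expect_equal(nrow(iv$pairs), 1)
  expect_true(all(iv$pairs$pval_exp < 5e-8))
  expect_true(all(iv$pairs$f_stat > 10))

  # sub-threshold p
  weak <- make_snps(1, beta = 0.1, se = 0.02)   # p ~ 5.7e-7
  iv <- select_instruments(make_region(weak), out_region(weak), crit)
  expect_equal(nrow(iv$pairs), 0)

  # MHC exclusion: chr 6 at 30 Mb
  mhc <- make_snps(1, chr = "6", pos = 3e7, beta = 0.1, se = 0.01)
  iv <- select_instruments(
    make_region(mhc, gene_chrom = "6", gene_start = 3e7 - 1e4,
                gene_end = 3e7 + 1e4),
    out_region(mhc), crit)
  expect_equal(nrow(iv$pairs), 0)
  expect_equal(iv$attrition$n_after[iv$attrition$stage == "mhc"], 0)

  # outside the cis window
  far <- make_snps(1, pos = 1e6 + 2.1e6, beta = 0.1, se = 0.01)
  iv <- select_instruments(make_region(far), out_region(far), crit)
  expect_equal(iv$attrition$n_after[iv$attrition$stage == "cis"], 0)
})

test_that("an F-statistic at or below 10 excludes the instrument", {
  n <- 50000
  # choose z so that F = 9.9 (just below) and 10.1 (just above):
  # F = (n-2) z^2 / n for a single SNP, so z^2 = F n / (n - 2)
  for (f_target in c(9.9, 10.1)) {
    z2 <- f_target * n / (n - 2)
    df <- make_snps(1, beta = sqrt(z2) * 0.01, se = 0.01, n_gwas = n)
    df$pval <- 1e-9  # force past the p filter; keep |z| consistency off
    region <- region_dataset(df, "prot", "protein", gene_chrom = "1",
                             gene_start = 1e6, gene_end = 1.02e6,
                             validate = FALSE)
    out <- region_dataset(df, "out", "outcome", validate = FALSE)
    iv <- select_instruments(region, out, instrument_criteria())
    expect_equal(nrow(iv$pairs), if (f_target > 10) 1 else 0)
  }
})

test_that("selection is invariant under input row shuffling", {
  spec <- scenario_spec("shared_causal", m_snps = 20, ld_rho = 0.6,
                        causal_index = c(4, 16), theta = 0.2,
                        n_exposure = 1e5, n_outcome = 1e5, seed = 5)
  r <- simulate_region(spec)
  iv1 <- select_instruments(r$exposure, r$outcome)
  set.seed(1)
  shuf <- r$exposure
  perm <- sample(nrow(shuf$snps))
  shuf$snps <- shuf$snps[perm, ]
  rownames(shuf$snps) <- NULL
  iv2 <- select_instruments(shuf, r$outcome)
  expect_equal(iv1$pairs, iv2$pairs)
})
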
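# Simulation of GWAS summary statistics over a cis region under LD.
#
# Marginal z-scores are drawn from the standard summary-statistic model: if
# b_j are joint (causal) per-allele effects on a standardized trait, the
# joint z-scores are z_joint_j = b_j * sqrt(2 n f_j (1 - f_j)) and the
# marginal z-scores follow a multivariate normal with mean R %*% z_joint and
# covariance R, where R is the LD correlation matrix. Per-SNP standard
# errors are 1 / sqrt(2 n f_j (1 - f_j)); betas, p-values and frequencies
# follow. Everything is deterministic given the scenario seed.

#' AR(1) LD correlation matrix
#'
#' `r[i, j] = rho^|i - j|`; positive definite by construction for
#' `0 <= rho < 1`.
#'
#' @param m_snps Number of SNPs.
#' @param rho AR(1) correlation parameter in \[0, 1).
#' @param snp_ids Row/column names. Default `snp_1 .. snp_m`.
#' @return Named square correlation matrix.
#' @export
make_ld <- function(m_snps, rho, snp_ids = paste0("snp_", seq_len(m_snps))) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  idx <- seq_len(m_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Scenario specification for the region simulator
#'
#' Defines the data-generating conditions for one cis region. Defaults
#' reflect the structure of large proteogenomic studies: cis regions of ~50
#' correlated variants, a strong cis-pQTL (per-allele effect 0.15 SD on the
#' protein), a protein GWAS of ~33,000 participants and a quantitative
#' outcome GWAS of ~426,800 (with sex strata of roughly 225,000 female and
#' 200,000 male), and a mediator GWAS of ~461,500.
#'
#' @param scenario One of `"null"` (cis-pQTL present, no effect on the
#'   outcome), `"shared_causal"` (outcome effects are `theta` times the
#'   exposure effects at the same causal variants), `"linkage"` (the outcome
#'   has its own causal variant in LD with the exposure's), `"reverse"` (the
#'   outcome drives the region; the exposure inherits `theta` times its
#'   effects), `"mediation_chain"` (exposure -> mediator -> outcome with
#'   coefficients `a`, `b` and direct effect `c_direct`), or
#'   `"sex_specific"` (female/male outcome effects `theta_f`, `theta_m`).
#' @param m_snps Number of SNPs in the region.
#' @param maf_range Range of minor-allele frequencies, sampled uniformly.
#' @param ld_rho AR(1) LD parameter in \[0, 1).
#' @param beta_causal Per-allele effect of the causal variant(s) on the
#'   exposure (SD units).
#' @param causal_index Index (or vector of indices) of exposure causal
#'   SNP(s). Default: the middle SNP.
#' @param theta True causal effect of exposure on outcome (SD per SD); under
#'   `"reverse"`, of outcome on exposure.
#' @param beta_causal_outcome Per-allele effect of the outcome's own causal
#'   variant under `"linkage"`.
#' @param linkage_r2 Target squared LD between the exposure and outcome
#'   causal variants under `"linkage"`; the realized value is the closest on
#'   the AR(1) grid.
#' @param a,b,c_direct Mediation-chain coefficients: exposure -> mediator
#'   (`a`), mediator -> outcome (`b`), direct exposure -> outcome
#'   (`c_direct`).
#' @param theta_f,theta_m Sex-specific causal effects.
#' @param n_exposure,n_outcome,n_mediator,n_female,n_male GWAS sample sizes.
#' @param gene_chrom,gene_start,gene_end Coding-gene coordinates; SNPs span
#'   the gene plus 500 kb each side.
#' @param palindrome_fraction Fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs. Default 0.15.
#' @param seed Integer seed; all child draws derive from it.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("null", "shared_causal", "linkage",
                                       "reverse", "mediation_chain",
                                       "sex_specific"),
                          m_snps = 50, maf_range = c(0.05, 0.5),
                          ld_rho = 0.8, beta_causal = 0.15,
                          causal_index = NULL, theta = 0.3,
                          beta_causal_outcome = 0.05, linkage_r2 = 0.5,
                          a = 0.02, b = 0.1, c_direct = 0.03,
                          theta_f = 0.20, theta_m = 0.04,
                          n_exposure = 33000, n_outcome = 426824,
                          n_mediator = 461460, n_female = 225000,
                          n_male = 200000, gene_chrom = "11",
                          gene_start = 1e6, gene_end = 1.02e6,
                          palindrome_fraction = 0.15, seed = 1) {
  scenario <- match.arg(scenario)
  causal_index <- causal_index %||% ceiling(m_snps / 2)
  stopifnot(m_snps >= 1, all(causal_index >= 1), all(causal_index <= m_snps),
            ld_rho >= 0, ld_rho < 1, n_exposure > 10, n_outcome > 10,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            palindrome_fraction >= 0, palindrome_fraction <= 1)
  structure(
    list(scenario = scenario, m_snps = m_snps, maf_range = maf_range,
         ld_rho = ld_rho, beta_causal = beta_causal,
         causal_index = causal_index, theta = theta,
         beta_causal_outcome = beta_causal_outcome, linkage_r2 = linkage_r2,
         a = a, b = b, c_direct = c_direct, theta_f = theta_f,
         theta_m = theta_m, n_exposure = n_exposure, n_outcome = n_outcome,
         n_mediator = n_mediator, n_female = n_female, n_male = n_male,
         gene_chrom = as.character(gene_chrom), gene_start = gene_start,
         gene_end = gene_end, palindrome_fraction = palindrome_fraction,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# Region-level fixed quantities shared by all traits: frequencies,
# positions, alleles, LD and its Cholesky factor.
sim_region_meta <- function(spec) {
  set.seed(child_seed(spec$seed, 0L))
  m <- spec$m_snps
  f <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  span_lo <- spec$gene_start - 5e5
  span_hi <- spec$gene_end + 5e5
  pos <- round(seq(span_lo, span_hi, length.out = m))
  ids <- sprintf("rs%04d", seq_len(m))
  pal <- stats::runif(m) < spec$palindrome_fraction
  ea <- character(m)
  oa <- character(m)
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pick_pal <- sample.int(4, m, replace = TRUE)
  pick_non <- sample.int(8, m, replace = TRUE)
  ea <- ifelse(pal, pal_pairs[pick_pal, 1], nonpal[pick_non, 1])
  oa <- ifelse(pal, pal_pairs[pick_pal, 2], nonpal[pick_non, 2])
  ld <- make_ld(m, spec$ld_rho, ids)
  list(m = m, f = f, pos = pos, ids = ids, ea = ea, oa = oa, ld = ld,
       chol_u = chol(ld))
}

# One trait's marginal summary statistics given joint per-allele effects.
sim_trait <- function(meta, spec, n, b_joint, stream, trait_id, trait_kind) {
  set.seed(child_seed(spec$seed, stream))
  s <- 1 / sqrt(2 * n * meta$f * (1 - meta$f))
  z_joint <- b_joint / s
  z <- as.vector(meta$ld %*% z_joint +
                   crossprod(meta$chol_u, stats::rnorm(meta$m)))
  beta <- z * s
  snps <- data.frame(
    snp = meta$ids, chr = spec$gene_chrom, pos = meta$pos, ea = meta$ea,
    oa = meta$oa, eaf = meta$f, beta = beta, se = s, pval = two_sided_p(z),
    n = n, stringsAsFactors = FALSE
  )
  region_dataset(snps, trait_id = trait_id, trait_kind = trait_kind,
                 gene_chrom = spec$gene_chrom, gene_start = spec$gene_start,
                 gene_end = spec$gene_end, ld = meta$ld)
}

# Joint effect vectors per trait implied by a scenario.
scenario_effects <- function(spec, m) {
  bx <- numeric(m)
  by <- numeric(m)
  bm <- NULL
  bf <- NULL
  bmale <- NULL
  ci <- spec$causal_index
  switch(spec$scenario,
    null = {
      bx[ci] <- spec$beta_causal
    },
    shared_causal = {
      bx[ci] <- spec$beta_causal
      by <- spec$theta * bx
    },
    linkage = {
      bx[ci] <- spec$beta_causal
      d <- if (spec$ld_rho == 0) 1L else
        max(1L, as.integer(round(log(spec$linkage_r2) /
                                   (2 * log(spec$ld_rho)))))
      cj <- pmin(m, ci + d)
      by[cj] <- spec$beta_causal_outcome
    },
    reverse = {
      by[ci] <- spec$beta_causal
      bx <- spec$theta * by
    },
    mediation_chain = {
      bx[ci] <- spec$beta_causal
      bm <- spec$a * bx
      by <- (spec$a * spec$b + spec$c_direct) * bx
    },
    sex_specific = {
      bx[ci] <- spec$beta_causal
      bf <- spec$theta_f * bx
      bmale <- spec$theta_m * bx
      by <- 0.5 * (spec$theta_f + spec$theta_m) * bx
    }
  )
  list(exposure = bx, outcome = by, mediator = bm, outcome_female = bf,
       outcome_male = bmale)
}

#' Simulate summary statistics for one cis region
#'
#' Draws per-trait marginal summary statistics for the traits implied by the
#' scenario (always `exposure` and `outcome`; plus `mediator` for the
#' mediation chain, and `outcome_female`/`outcome_male` for the sex-specific
#' scenario). Each trait uses an independent child stream of `spec$seed`, so
#' output is deterministic given the seed and adding a trait does not
#' perturb the others.
#'
#' @param spec A [scenario_spec()].
#' @return Named list of `region_dataset` objects sharing SNP ids, alleles,
#'   frequencies and LD.
#' @export
simulate_region <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  meta <- sim_region_meta(spec)
  eff <- scenario_effects(spec, meta$m)
  out <- list(
    exposure = sim_trait(meta, spec, spec$n_exposure, eff$exposure, 1L,
                         "exposure", "protein"),
    outcome = sim_trait(meta, spec, spec$n_outcome, eff$outcome, 2L,
                        "outcome", "outcome")
  )
  if (!is.null(eff$mediator)) {
    out$mediator <- sim_trait(meta, spec, spec$n_mediator, eff$mediator, 3L,
                              "mediator", "mediator")
  }
  if (!is.null(eff$outcome_female)) {
    out$outcome_female <- sim_trait(meta, spec, spec$n_female,
                                    eff$outcome_female, 4L,
                                    "outcome_female", "outcome")
    out$outcome_male <- sim_trait(meta, spec, spec$n_male,
                                  eff$outcome_male, 5L,
                                  "outcome_male", "outcome")
  }
  out
}

#' Simulate a full study input bundle
#'
#' Writes a self-consistent directory of tab-separated inputs for
#' [run_pipeline()]: per-protein cis-region summary statistics for the
#' protein, the outcome, the sex-stratified outcomes and the mediator, with
#' per-region LD matrices; plus a separate mediator cis region (for the
#' mediator -> outcome step of mediation MR) and a YAML manifest recording
#' the layout and the ground truth (scenario and true effects per protein).
#'
#' The first `n_positive` proteins have a true causal effect `theta` on the
#' outcome (and, when mediation is included, a mediated component through
#' the mediator with step-1 coefficient `a`); the remainder carry a cis-pQTL
#' but no outcome effect. When `sex_specific_first = TRUE` the first protein
#' gets sex-specific effects `theta_f`/`theta_m` instead of `theta` in the
#' sex strata.
#'
#' @param out_dir Output directory (created if needed).
#' @param protein_count Number of proteins (>= 1).
#' @param n_positive Number with a true effect.
#' @param seed Global integer seed.
#' @param theta True causal effect for positive proteins.
#' @param n_exposure,n_outcome GWAS sample sizes for proteins and outcome.
#' @param m_snps,ld_rho,beta_causal,maf_range Region structure (see
#'   [scenario_spec()]).
#' @param include_mediator,include_sex Write mediator and sex-stratified
#'   files.
#' @param sex_specific_first Give protein 1 sex-specific effects.
#' @param a Protein -> mediator coefficient for positive proteins.
#' @param b Mediator -> outcome causal effect (mediator region).
#' @param n_mediator Mediator GWAS sample size.
#' @param theta_f,theta_m Sex-specific effects for the first protein.
#' @return The manifest, invisibly.
#' @export
simulate_study <- function(out_dir, protein_count = 10, n_positive = 3,
                           seed = 1, theta = 0.3, n_exposure = 1e5,
                           n_outcome = 1e5, m_snps = 50, ld_rho = 0.8,
                           beta_causal = 0.15, maf_range = c(0.05, 0.5),
                           include_mediator = TRUE, include_sex = TRUE,
                           sex_specific_first = TRUE, a = 0.02, b = 0.1,
                           n_mediator = 461460, theta_f = 0.20,
                           theta_m = 0.04) {
  stopifnot(protein_count >= 1, n_positive >= 0,
            n_positive <= protein_count)
  dirs <- c("proteins", "outcome", "ld")
  if (include_mediator) dirs <- c(dirs, "mediator", "mediator_region")
  if (include_sex) dirs <- c(dirs, "outcome_female", "outcome_male")
  for (d in dirs) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }

  proteins <- vector("list", protein_count)
  for (i in seq_len(protein_count)) {
    id <- sprintf("P%03d", i)
    positive <- i <= n_positive
    theta_i <- if (positive) theta else 0
    a_i <- if (positive) a else 0
    sexspec <- sex_specific_first && i == 1 && positive
    tf_i <- if (sexspec) theta_f else theta_i
    tm_i <- if (sexspec) theta_m else theta_i
    chrom <- as.character(c(1, 2, 3, 4, 5, 7)[1 + (i - 1) %% 6])
    gstart <- 1e6 + ((i - 1) %% 4) * 6e6
    spec_i <- scenario_spec(
      scenario = "shared_causal", m_snps = m_snps, maf_range = maf_range,
      ld_rho = ld_rho, beta_causal = beta_causal, theta = theta_i,
      n_exposure = n_exposure, n_outcome = n_outcome,
      n_mediator = n_mediator, n_female = round(n_outcome / 2),
      n_male = round(n_outcome / 2), gene_chrom = chrom,
      gene_start = gstart, gene_end = gstart + 2e4,
      seed = child_seed(seed, i)
    )
    meta <- sim_region_meta(spec_i)
    bx <- numeric(m_snps)
    bx[spec_i$causal_index] <- beta_causal
    traits <- list(exposure = sim_trait(meta, spec_i, n_exposure, bx, 1L,
                                        id, "protein"),
                   outcome = sim_trait(meta, spec_i, n_outcome,
                                       theta_i * bx, 2L, "outcome",
                                       "outcome"))
    if (include_mediator) {
      traits$mediator <- sim_trait(meta, spec_i, n_mediator, a_i * bx, 3L,
                                   "mediator", "mediator")
    }
    if (include_sex) {
      traits$outcome_female <- sim_trait(meta, spec_i, spec_i$n_female,
                                         tf_i * bx, 4L, "outcome_female",
                                         "outcome")
      traits$outcome_male <- sim_trait(meta, spec_i, spec_i$n_male,
                                       tm_i * bx, 5L, "outcome_male",
                                       "outcome")
    }

    files <- list(exposure = file.path("proteins", paste0(id, ".tsv")),
                  outcome = file.path("outcome", paste0(id, ".tsv")),
                  ld = file.path("ld", paste0(id, ".tsv")))
    write_summary_table(traits$exposure, file.path(out_dir, files$exposure))
    write_summary_table(traits$outcome, file.path(out_dir, files$outcome))
    write_ld_matrix(meta$ld, file.path(out_dir, files$ld))
    if (include_mediator) {
      files$mediator <- file.path("mediator", paste0(id, ".tsv"))
      write_summary_table(traits$mediator, file.path(out_dir,
                                                     files$mediator))
    }
    if (include_sex) {
      files$outcome_female <- file.path("outcome_female",
                                        paste0(id, ".tsv"))
      files$outcome_male <- file.path("outcome_male", paste0(id, ".tsv"))
      write_summary_table(traits$outcome_female,
                          file.path(out_dir, files$outcome_female))
      write_summary_table(traits$outcome_male,
                          file.path(out_dir, files$outcome_male))
    }

    proteins[[i]] <- list(
      id = id, gene_chrom = chrom, gene_start = gstart,
      gene_end = gstart + 2e4, files = files,
      truth = list(scenario = if (positive) "shared_causal" else "null",
                   theta = theta_i, a = a_i, theta_f = tf_i,
                   theta_m = tm_i)
    )
  }

  manifest <- list(seed = seed, protein_count = protein_count,
                   proteins = proteins)

  if (include_mediator) {
    med_spec <- scenario_spec(
      scenario = "shared_causal", m_snps = m_snps, maf_range = maf_range,
      ld_rho = ld_rho, beta_causal = 0.15, theta = b,
      n_exposure = n_mediator, n_outcome = n_outcome, gene_chrom = "16",
      gene_start = 53e6, gene_end = 53.02e6,
      seed = child_seed(seed, protein_count + 1L)
    )
    med <- simulate_region(med_spec)
    med$exposure$trait_id <- "mediator"
    med$exposure$trait_kind <- "mediator"
    med_files <- list(
      exposure = file.path("mediator_region", "mediator.tsv"),
      outcome = file.path("mediator_region", "outcome.tsv"),
      ld = file.path("mediator_region", "ld.tsv")
    )
    write_summary_table(med$exposure, file.path(out_dir,
                                                med_files$exposure))
    write_summary_table(med$outcome, file.path(out_dir, med_files$outcome))
    write_ld_matrix(med$exposure$ld, file.path(out_dir, med_files$ld))
    manifest$mediator_region <- list(
      gene_chrom = "16", gene_start = 53e6, gene_end = 53.02e6,
      files = med_files, truth = list(b = b)
    )
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
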
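# End-to-end orchestration: instruments -> MR -> Bonferroni -> SMR(+HEIDI)
# -> colocalization -> Steiger/reverse -> optional mediation and subgroup
# comparison, with a ranked, tiered per-protein results table.

#' Pipeline configuration
#'
#' @param input_dir Directory containing a `manifest.yaml` written by
#'   [simulate_study()] (or hand-assembled with the same layout).
#' @param out_dir Optional output directory for the per-stage TSVs and run
#'   log; nothing is written when `NULL`.
#' @param criteria An [instrument_criteria()].
#' @param priors A [coloc_priors()].
#' @param alpha Family-wise error rate for the MR Bonferroni correction and
#'   the nominal significance level elsewhere. Default 0.05.
#' @param smr_m Divisor for the SMR Bonferroni threshold; defaults to the
#'   number of MR-significant proteins in the run.
#' @param heidi_alpha HEIDI significance level; a protein passes HEIDI when
#'   its p-value is missing or `>= heidi_alpha`. Default 0.05.
#' @param random_effects,second_order Estimator flags (see [ivw()],
#'   [wald_ratio()]).
#' @param run_reverse,run_mediation,run_subgroup Stage switches.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir = NULL,
                            criteria = instrument_criteria(),
                            priors = coloc_priors(), alpha = 0.05,
                            smr_m = NULL, heidi_alpha = 0.05,
                            random_effects = FALSE, second_order = FALSE,
                            run_reverse = TRUE, run_mediation = TRUE,
                            run_subgroup = TRUE) {
  manifest <- file.path(input_dir, "manifest.yaml")
  if (!file.exists(manifest)) {
    stop("no manifest.yaml under input_dir: ", input_dir)
  }
  structure(
    list(input_dir = input_dir, out_dir = out_dir, criteria = criteria,
         priors = priors, alpha = alpha, smr_m = smr_m,
         heidi_alpha = heidi_alpha, random_effects = random_effects,
         second_order = second_order, run_reverse = run_reverse,
         run_mediation = run_mediation, run_subgroup = run_subgroup),
    class = "pipeline_config"
  )
}

#' Evidence tier for a protein
#'
#' A protein reaches the strong-evidence tier iff it passes the MR
#' Bonferroni threshold, passes the SMR Bonferroni threshold, shows strong
#' colocalization (`PP.H4 >= 0.80`), has the supported causal direction
#' (Steiger), and is not rejected by HEIDI (p-value missing or
#' `>= heidi_alpha`). Vectorized; any missing prerequisite other than the
#' HEIDI p-value demotes to `"none"`.
#'
#' @param pass_bonferroni,pass_smr_bonferroni Logical.
#' @param pp_h4 Posterior probability of a shared causal variant.
#' @param direction_ok Logical from the Steiger test.
#' @param heidi_pval HEIDI p-value (`NA` allowed).
#' @param heidi_alpha HEIDI significance level. Default 0.05.
#' @return Character vector, `"strong"` or `"none"`.
#' @export
evidence_tier <- function(pass_bonferroni, pass_smr_bonferroni, pp_h4,
                          direction_ok, heidi_pval, heidi_alpha = 0.05) {
  ok <- !is.na(pass_bonferroni) & pass_bonferroni &
    !is.na(pass_smr_bonferroni) & pass_smr_bonferroni &
    !is.na(pp_h4) & pp_h4 >= 0.80 &
    !is.na(direction_ok) & direction_ok &
    (is.na(heidi_pval) | heidi_pval >= heidi_alpha)
  ifelse(ok, "strong", "none")
}

read_region_file <- function(input_dir, rel_path, trait_id, trait_kind,
                             gene_chrom, gene_start, gene_end, ld = NULL) {
  read_summary_table(file.path(input_dir, rel_path), trait_id = trait_id,
                     trait_kind = trait_kind, gene_chrom = gene_chrom,
                     gene_start = gene_start, gene_end = gene_end, ld = ld)
}

# Forward MR for one protein entry of the manifest; shared by the main run
# and external validation.
forward_fit <- function(input_dir, entry, criteria, random_effects = FALSE,
                        second_order = FALSE) {
  ld <- read_ld_matrix(file.path(input_dir, entry$files$ld))
  protein <- read_region_file(input_dir, entry$files$exposure, entry$id,
                              "protein", entry$gene_chrom, entry$gene_start,
                              entry$gene_end, ld = ld)
  outcome <- read_region_file(input_dir, entry$files$outcome, "outcome",
                              "outcome", entry$gene_chrom, entry$gene_start,
                              entry$gene_end)
  iv <- select_instruments(protein, outcome, criteria)
  fit <- mr_fit(iv$pairs, random_effects = random_effects,
                second_order = second_order, exposure_id = entry$id,
                outcome_id = "outcome")
  list(protein = protein, outcome = outcome, iv = iv, fit = fit)
}

#' Run the full proteome-MR pipeline
#'
#' Executes, per protein: instrument selection, forward MR, SMR with HEIDI,
#' colocalization, Steiger directionality, and (optionally) reverse MR,
#' two-step mediation through the mediator region, and the sex-stratified
#' subgroup comparison. MR significance is Bonferroni-controlled across the
#' proteins actually tested; the SMR Bonferroni divisor defaults to the
#' number of MR-significant proteins. Deterministic given the inputs; when
#' `config$out_dir` is set, per-stage TSVs and a run log with attrition
#' counts are written.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `protein_report_set`: list with `results` (one
#'   row per protein, ordered by descending PP.H4 then ascending MR p),
#'   `mediation`, `subgroup`, `attrition`, `bonferroni`, `smr_bonferroni`
#'   and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- yaml::read_yaml(file.path(config$input_dir, "manifest.yaml"))
  criteria <- config$criteria
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  step2 <- NULL
  if (config$run_mediation && !is.null(manifest$mediator_region)) {
    mr_ent <- manifest$mediator_region
    med_ld <- read_ld_matrix(file.path(config$input_dir, mr_ent$files$ld))
    med_exp <- read_region_file(config$input_dir, mr_ent$files$exposure,
                                "mediator", "mediator", mr_ent$gene_chrom,
                                mr_ent$gene_start, mr_ent$gene_end,
                                ld = med_ld)
    med_out <- read_region_file(config$input_dir, mr_ent$files$outcome,
                                "outcome", "outcome", mr_ent$gene_chrom,
                                mr_ent$gene_start, mr_ent$gene_end)
    step2 <- mr_fit(select_instruments(med_exp, med_out, criteria)$pairs,
                    exposure_id = "mediator", outcome_id = "outcome")
    say("mediator region: step-2 beta=%.4g se=%.4g (%d SNPs)", step2$beta,
        step2$se, step2$n_snp)
  }

  rows <- list()
  med_rows <- list()
  sub_rows <- list()
  att_rows <- list()

  for (entry in manifest$proteins) {
    id <- entry$id
    fw <- forward_fit(config$input_dir, entry, criteria,
                      config$random_effects, config$second_order)
    att <- fw$iv$attrition
    att$protein <- id
    att_rows[[id]] <- att[, c("protein", "stage", "n_before", "n_after")]
    say("%s: instruments %d -> %d", id, att$n_before[1],
        nrow(fw$iv$pairs))

    status <- if (nrow(fw$iv$pairs) == 0) "no_instrument" else "ok"
    fit <- fw$fit
    steiger <- steiger_directionality(fw$iv$pairs)

    smr <- smr_test(fw$protein, fw$outcome)
    heidi <- list(heidi_pval = NA_real_, n_snps_used = 0L)
    if (!is.na(smr$top_snp)) {
      heidi <- heidi_test(fw$protein, fw$outcome, fw$protein$ld)
    }

    col <- tryCatch(coloc_abf(fw$protein, fw$outcome, config$priors),
                    error = function(e) NULL)
    pp <- if (is.null(col)) rep(NA_real_, 5) else unname(col$pp)

    rev_beta <- NA_real_
    rev_pval <- NA_real_
    rev_nsnp <- NA_integer_
    if (config$run_reverse) {
      out_as_exp <- fw$outcome
      out_as_exp$gene_chrom <- fw$protein$gene_chrom
      out_as_exp$gene_start <- fw$protein$gene_start
      out_as_exp$gene_end <- fw$protein$gene_end
      out_as_exp$ld <- fw$protein$ld
      rev <- reverse_mr(out_as_exp, fw$protein, criteria)
      rev_beta <- rev$beta
      rev_pval <- rev$pval
      rev_nsnp <- rev$n_snp
    }

    if (config$run_mediation && !is.null(step2) &&
        !is.null(entry$files$mediator) && status == "ok" &&
        !is.na(fit$beta)) {
      med_ds <- read_region_file(config$input_dir, entry$files$mediator,
                                 "mediator", "mediator", entry$gene_chrom,
                                 entry$gene_start, entry$gene_end)
      prot_ld <- fw$protein
      step1 <- mr_fit(select_instruments(prot_ld, med_ds, criteria)$pairs,
                      exposure_id = id, outcome_id = "mediator")
      if (!is.na(step1$beta)) {
        med_rows[[id]] <- two_step_mediation(step1, step2, fit)
      }
    }

    if (config$run_subgroup && !is.null(entry$files$outcome_female) &&
        !is.null(entry$files$outcome_male) && status == "ok") {
      fem <- read_region_file(config$input_dir, entry$files$outcome_female,
                              "outcome_female", "outcome", entry$gene_chrom,
                              entry$gene_start, entry$gene_end)
      mal <- read_region_file(config$input_dir, entry$files$outcome_male,
                              "outcome_male", "outcome", entry$gene_chrom,
                              entry$gene_start, entry$gene_end)
      fit_f <- mr_fit(select_instruments(fw$protein, fem, criteria)$pairs,
                      exposure_id = id, outcome_id = "outcome_female")
      fit_m <- mr_fit(select_instruments(fw$protein, mal, criteria)$pairs,
                      exposure_id = id, outcome_id = "outcome_male")
      if (!is.na(fit_f$beta) && !is.na(fit_m$beta)) {
        cmp <- subgroup_z_test(fit_f$beta, fit_f$se, fit_m$beta, fit_m$se)
        cmp <- cbind(protein = id, cmp,
                     pval_f = fit_f$pval, pval_m = fit_m$pval)
        sub_rows[[id]] <- cmp
      }
    }

    rows[[id]] <- data.frame(
      protein = id, status = status, method = fit$method,
      n_snp = fit$n_snp, beta = fit$beta, se = fit$se,
      ci_low = fit$ci_low, ci_high = fit$ci_high, pval = fit$pval,
      steiger_pval = steiger$pval,
      direction_ok = if (is.null(steiger$direction_ok)) NA else
        steiger$direction_ok,
      smr_top_snp = smr$top_snp, beta_smr = smr$beta_smr,
      se_smr = smr$se_smr, pval_smr = smr$pval_smr,
      heidi_pval = heidi$heidi_pval, n_heidi_snps = heidi$n_snps_used,
      pp_h0 = pp[1], pp_h1 = pp[2], pp_h2 = pp[3], pp_h3 = pp[4],
      pp_h4 = pp[5],
      coloc_tier = if (is.null(col)) NA_character_ else col$tier,
      reverse_beta = rev_beta, reverse_pval = rev_pval,
      reverse_n_snp = rev_nsnp,
      stringsAsFactors = FALSE
    )
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  m_tested <- sum(!is.na(results$pval))
  bthr <- bonferroni_threshold(config$alpha, max(m_tested, 1L))
  results$pass_bonferroni <- !is.na(results$pval) & results$pval < bthr
  m_smr <- config$smr_m %||% max(1L, sum(results$pass_bonferroni))
  sthr <- bonferroni_threshold(config$alpha, m_smr)
  results$pass_smr_bonferroni <- !is.na(results$pval_smr) &
    results$pval_smr < sthr
  results$tier <- evidence_tier(results$pass_bonferroni,
                                results$pass_smr_bonferroni, results$pp_h4,
                                results$direction_ok, results$heidi_pval,
                                config$heidi_alpha)
  ord <- order(-ifelse(is.na(results$pp_h4), -Inf, results$pp_h4),
               ifelse(is.na(results$pval), Inf, results$pval),
               results$protein)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL

  mediation <- if (length(med_rows)) do.call(rbind, med_rows) else NULL
  subgroup <- if (length(sub_rows)) do.call(rbind, sub_rows) else NULL
  attrition <- do.call(rbind, att_rows)
  rownames(attrition) <- NULL
  say("tested %d proteins; MR Bonferroni %.4g; SMR Bonferroni %.4g",
      m_tested, bthr, sthr)
  say("strong-evidence proteins: %d", sum(results$tier == "strong"))

  report <- structure(
    list(results = results, mediation = mediation, subgroup = subgroup,
         attrition = attrition, bonferroni = bthr, smr_bonferroni = sthr,
         log = log_lines, config = config),
    class = "protein_report_set"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    if (!is.null(x)) {
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$results, "results.tsv")
  wt(report$mediation, "mediation.tsv")
  wt(report$subgroup, "subgroup.tsv")
  wt(report$attrition, "attrition.tsv")
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.protein_report_set <- function(x, ...) {
  cat(sprintf("<protein_report_set> %d proteins, %d strong-evidence\n",
              nrow(x$results), sum(x$results$tier == "strong")))
  invisible(x)
}

#' External validation rerun on alternative inputs
#'
#' Reruns the forward MR only, against an alternative input bundle (for
#' example a replication cohort's pQTLs or an alternative outcome GWAS), and
#' flags replication at the nominal level with direction concordance.
#' Proteins absent from the alternative bundle are recorded as
#' `not_testable`.
#'
#' @param config A [pipeline_config()] for the original inputs.
#' @param alt_input_dir Directory with the alternative bundle (same layout).
#' @param report Optional [run_pipeline()] result for the original inputs;
#'   computed if missing.
#' @return Data frame with one row per original protein: `protein`,
#'   original beta, validation `beta`, `pval`, `n_snp` and `status`
#'   (`replicated`, `not_replicated`, `not_testable`, `no_instrument`).
#' @export
external_validation_run <- function(config, alt_input_dir, report = NULL) {
  if (is.null(report)) report <- run_pipeline(config)
  alt_manifest <- yaml::read_yaml(file.path(alt_input_dir, "manifest.yaml"))
  alt_entries <- stats::setNames(alt_manifest$proteins,
                                 vapply(alt_manifest$proteins, `[[`,
                                        character(1), "id"))
  orig <- report$results
  out <- vector("list", nrow(orig))
  for (i in seq_len(nrow(orig))) {
    id <- orig$protein[i]
    row <- data.frame(protein = id, beta_original = orig$beta[i],
                      beta = NA_real_, pval = NA_real_,
                      n_snp = NA_integer_, status = "not_testable",
                      stringsAsFactors = FALSE)
    entry <- alt_entries[[id]]
    if (!is.null(entry) && !is.na(orig$beta[i])) {
      fw <- forward_fit(alt_input_dir, entry, config$criteria,
                        config$random_effects, config$second_order)
      row$beta <- fw$fit$beta
      row$pval <- fw$fit$pval
      row$n_snp <- fw$fit$n_snp
      row$status <- if (is.na(fw$fit$beta)) {
        "no_instrument"
      } else if (fw$fit$pval < config$alpha &&
                 sign(fw$fit$beta) == sign(orig$beta[i])) {
        "replicated"
      } else {
        "not_replicated"
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
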
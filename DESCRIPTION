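Package: protmr
Title: Proteome-Wide Mendelian Randomization with cis-pQTL Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization of plasma protein levels on
    complex-trait outcomes using cis-pQTL instruments. Provides allele
    harmonization for GWAS summary statistics, instrument selection
    (genome-wide significance, LD clumping, cis-window and MHC filters,
    F-statistic screening), Wald-ratio and inverse-variance-weighted causal
    estimation with Bonferroni control, summary-data-based MR (SMR) with the
    HEIDI linkage-heterogeneity test, approximate-Bayes-factor colocalization
    over five hypotheses, Steiger directionality and reverse-MR checks,
    two-step mediation analysis with delta-method standard errors,
    sex-stratified effect comparison, a summary-statistic simulator with
    realistic LD structure for validating every stage, and an end-to-end
    pipeline that ranks proteins by tiers of causal evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
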
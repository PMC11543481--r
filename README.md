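# protmr

Proteome-wide Mendelian randomization (MR) with *cis*-pQTL instruments,
in R.

## What problem this solves

Plasma proteins are the largest class of druggable targets, and
protein quantitative trait loci (pQTLs) near a protein's coding gene
make natural genetic instruments for asking whether the protein
*causes* a disease trait — here, a quantitative bone-density outcome —
rather than merely correlating with it. protmr implements the complete
two-sample MR screen a practitioner runs over GWAS summary statistics,
for analysts who have per-protein cis-region summary statistics, an
outcome GWAS, and per-region LD matrices, and who want every
published-style robustness check in one tested, deterministic pipeline.

The core machinery, in the field's standard notation:

* **Instrument selection** — cis SNPs with association
  *P* < 5×10⁻⁸, within 1 Mb of the gene body, outside the MHC
  (chr 6, 26–34 Mb), LD-clumped to *r*² < 0.001, with per-SNP
  F-statistic > 10, after allele harmonization (palindromic SNPs with
  allele frequency within 0.08 of 0.5 are dropped).
* **Causal estimates** — the Wald ratio β_GY/β_GX for single
  instruments; fixed-effect IVW (weighted regression through the
  origin, weights 1/SE_GY²) for two or more; Bonferroni control across
  proteins.
* **SMR + HEIDI** — the top-cis-SNP statistic
  T_SMR = z_X²z_Y²/(z_X²+z_Y²) ~ χ²(1), and the HEIDI test that
  distinguishes one shared causal variant from linkage using the
  surrounding SNPs' ratio heterogeneity under a weighted-χ² law.
* **Colocalization** — Wakefield approximate Bayes factors per SNP,
  posterior probabilities for the five hypotheses H0–H4 with priors
  p1 = p2 = 10⁻⁴, p12 = 10⁻⁵; PP.H4 ≥ 0.80 is strong evidence,
  0.50–0.80 weak.
* **Directionality** — Steiger test (variance explained in exposure vs
  outcome, Fisher-z p-value) and reverse MR with the trait roles
  exchanged.
* **Mediation & subgroups** — two-step MR through a mediator (indirect
  effect a·b, delta-method SE √(a²se_b² + b²se_a²)) and a bilateral
  Z-test comparing sex-stratified effects.
* **Simulator** — GWAS summary statistics with realistic LD
  (z ~ MVN(R·z_joint, R), SE = 1/√(2nf(1−f))) under shared-causal,
  linkage, null, reverse, mediation-chain and sex-specific scenarios,
  so the entire pipeline is testable offline.

See `vignettes/proteome-mr-methods.Rmd` for models, assumptions,
defaults and design decisions.

## Worked example

Simulate a small study — five proteins, two with a true effect
θ = 0.3 on the outcome — and run the full pipeline:

```r
library(protmr)

dir <- file.path(tempdir(), "osteo_demo")
simulate_study(dir, protein_count = 5, n_positive = 2, seed = 42,
               theta = 0.3, n_exposure = 1e5, n_outcome = 1e5)
report <- run_pipeline(pipeline_config(dir, out_dir = file.path(dir, "results")))
report
#> <protein_report_set> 5 proteins, 2 strong-evidence

cols <- c("protein", "n_snp", "beta", "pval", "pval_smr", "heidi_pval",
          "pp_h4", "tier")
print(report$results[, cols], digits = 3)
#>   protein n_snp    beta     pval pval_smr heidi_pval   pp_h4   tier
#> 1    P002     1  0.2871 5.66e-17 8.49e-16     0.2820 1.00000 strong
#> 2    P001     1  0.3006 6.33e-13 5.63e-12     0.1894 1.00000 strong
#> 3    P004     1 -0.1004 4.62e-02 4.73e-02     0.0101 0.03496   none
#> 4    P003     1  0.0206 5.86e-01 5.86e-01     0.3656 0.00458   none
#> 5    P005     1  0.0287 3.56e-01 3.57e-01     0.0920 0.00457   none
```

Reading the table: each protein gets a causal estimate `beta` (SD of
outcome per SD of protein; P001's 0.30 recovers the simulated θ = 0.3),
its MR p-value against the run's Bonferroni threshold
(`report$bonferroni`, here 0.05/5 = 0.01), the SMR p-value, the HEIDI
p-value (≥ 0.05 means no evidence the signal is linkage rather than a
shared variant), and the colocalization posterior `pp_h4`. A protein is
tiered `strong` only when *all* of these support causality. The two
simulated positives are recovered; the three nulls are not flagged —
P004's nominal MR p ≈ 0.046 does not survive Bonferroni, its PP.H4 ≈
0.03 shows the protein and outcome signals do not share a variant, and
HEIDI agrees.

The first protein was simulated with sex-specific effects
(θ_f = 0.20, θ_m = 0.04), and the subgroup comparison finds the
difference:

```r
print(report$subgroup[report$subgroup$protein == "P001",
                      c("beta_f", "beta_m", "z_stat", "pval")], digits = 3)
#>      beta_f beta_m z_stat   pval
#> P001  0.201  0.033   2.01 0.0445
```

Per-stage TSVs (`results.tsv`, `attrition.tsv`, `mediation.tsv`,
`subgroup.tsv`) and a run log land under the `out_dir`. The same flow is
available from a shell:

```sh
Rscript inst/cli/protmr.R simulate --out demo --proteins 5 --positives 2 --seed 42
Rscript inst/cli/protmr.R run --in demo --out demo/results
Rscript inst/cli/protmr.R validate --in demo --alt demo_replication --out demo/validation.tsv
```

## Layout

```
R/                   implementation (summary stats & harmonization,
                     instruments, MR engine, SMR/HEIDI, coloc,
                     mediation/subgroup, simulator, pipeline)
tests/testthat/      unit, property and acceptance tests
scripts/acceptance.R headline-quantity reproduction (JSON out)
inst/cli/protmr.R    command-line wrapper (simulate / run / validate)
vignettes/           methods vignette
```
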
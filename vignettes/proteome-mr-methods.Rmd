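---
title: "Methods: proteome-wide Mendelian randomization with cis-pQTL instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide Mendelian randomization with cis-pQTL instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Setting

protmr screens plasma proteins for causal effects on a quantitative
outcome trait (the motivating application is heel bone mineral density
estimated by quantitative ultrasound) using two-sample Mendelian
randomization with *cis*-pQTL instruments. The inputs are GWAS summary
statistics only: per-SNP marginal effects for each protein over its
*cis* region, the same SNPs' effects on the outcome from an independent
GWAS, and a per-region LD correlation matrix. Because a protein's
*cis* variants act through the gene encoding it, they make biologically
plausible instruments, and the whole screen can run at proteome scale
from published summary data.

MR's causal interpretation rests on the usual instrumental-variable
assumptions: the variant is robustly associated with the protein
(relevance), shares no confounder with the outcome, and affects the
outcome only through the protein (no horizontal pleiotropy). The
pipeline does not assume these hold; it layers checks — colocalization,
HEIDI, Steiger directionality, reverse MR, external replication — whose
job is to catch the common failure modes (LD confounding with a distinct
causal variant, reverse causation, weak instruments).

## Instrument selection

`select_instruments()` applies five criteria in a fixed order, with
per-stage attrition recorded:

| criterion | default | unit / meaning |
|---|---|---|
| association p-value | `5e-8` | genome-wide significance for the protein |
| cis window | `1e6` bp | SNP within 1 Mb of the gene body (closed interval, 1-based positions) |
| MHC exclusion | chr 6, 26–34 Mb | removed for its complex LD |
| LD clumping | r² < `0.001` | greedy, strongest SNP first |
| F-statistic | > `10` | per-SNP weak-instrument screen |

Design notes:

* The *cis* window is anchored on the **gene body** — the interval
  `[gene_start − 1 Mb, gene_end + 1 Mb]` — rather than on the TSS or the
  gene midpoint. Gene coordinates are an input, not looked up.
* The F-statistic is computed per SNP (`k = 1`), from the variance
  explained `R² = 2f(1−f)β² / (2f(1−f)β² + 2f(1−f)·se²·n)`, which for a
  standardized trait reduces to `z²/(z²+n)` (the allele-frequency term
  cancels, so a missing frequency is tolerated).
* Clumping is greedy on ascending p-value. p-values are floored at
  `1e-300` to avoid log-domain underflow, so very strong cis signals tie
  at the floor; ties are therefore broken by **descending |z|**, then
  lexically by SNP id. Without the |z| tie-break a floored region would
  pick an arbitrary tag SNP as its lead variant, which measurably
  attenuates downstream ratio estimates. The same ranking defines the
  "top SNP" for SMR and HEIDI.

## Allele harmonization

Outcome records are aligned to the exposure's effect allele per SNP:
same-orientation pairs are kept; swapped alleles flip the outcome beta
and reflect its frequency; apparently incompatible non-palindromic pairs
are strand-complemented before being declared incompatible. Palindromic
SNPs (A/T, C/G) cannot be strand-resolved from labels, so they are
aligned by allele frequency and **dropped** when the minor-allele
frequency on either side is within `palindrome_af_window = 0.08` of 0.5
(or when a frequency is missing — conservative). The window matches
common two-sample MR practice; it is configurable. Rows violating basic
record invariants (non-ACGT or equal alleles, non-positive SE,
frequencies outside [0, 1], a reported p-value inconsistent with
|beta/se| beyond 10% relative tolerance on the log scale) are dropped
and counted, never silently repaired.

## Causal estimation

With one instrument the **Wald ratio** is used:
`beta = β_GY / β_GX`, `se = SE_GY / |β_GX|` (first-order delta — the
dominant convention; the second-order form that adds the
exposure-uncertainty term is available behind `second_order = TRUE`).
With two or more instruments the **fixed-effect IVW** estimator applies,
with weights `w_j = 1/SE_GY,j²`:

$$\hat\beta = \frac{\sum_j w_j \beta_{GX,j}\beta_{GY,j}}
                   {\sum_j w_j \beta_{GX,j}^2},\qquad
  se = \Big(\sum_j w_j \beta_{GX,j}^2\Big)^{-1/2},$$

identical to weighted least squares of the outcome effects on the
exposure effects through the origin. Fixed effects are the default
because cis-only instrument sets are small (usually 1–3 SNPs); a
multiplicative random-effects option scales the SE by the residual SD
when it exceeds 1. Confidence intervals use the normal multiplier
1.959964; family-wise error across proteins is controlled by Bonferroni
(`alpha / m`, with `m` the number of proteins actually tested). More
elaborate estimators (MR-Egger, weighted median/mode) are deliberately
out of scope: they need more instruments than cis regions provide.

## SMR and HEIDI

The SMR test uses the top cis-SNP only. With `z_X` and `z_Y` the
exposure and outcome z-scores,
`T_SMR = z_X² z_Y² / (z_X² + z_Y²)` is referred to χ²(1); in the limit
of an exactly measured exposure it reduces to the Wald-ratio test. The
SMR screen gets its own Bonferroni correction, with the divisor
defaulting to the number of MR-significant proteins in the run.

HEIDI asks whether the per-SNP ratio `b_i = β_GY,i / β_GX,i` is constant
across SNPs in LD with the top SNP — as it must be when one shared
causal variant drives both traits — or heterogeneous, as under linkage
of two distinct causal variants. Candidates are cis SNPs with exposure
`p < 1.57e-3`, squared correlation with the top SNP in `[0.05, 0.9]`,
capped at the 20 strongest (the defaults of the reference SMR software,
which documents the tool's knobs). For each candidate `d_i = b_i −
b_top`; the covariance of `d` follows from the first-order delta method
with `cov(β_i, β_j) = r_ij se_i se_j` within each trait (exposure and
outcome samples independent). The statistic `Q = Σ (d_i/SD(d_i))²` is
referred to the weighted-χ² law with weights the eigenvalues of the
correlation matrix of the standardized contrasts. The tail probability
uses Imhof's numeric inversion at tolerance `1e-8`, relaxing the
quadrature tolerance stepwise (to `1e-5`) when the oscillatory integral
hits roundoff, with Satterthwaite moment matching as the final fallback
— never a plain χ² approximation. Fewer than 3 usable candidates yield
no HEIDI p-value; the pipeline treats a missing HEIDI p as "not
rejected", and flags `p ≥ 0.05` as passing.

## Colocalization

`coloc_abf()` compares five hypotheses over the region — no causal
variant (H0), a causal variant for one trait only (H1/H2), two distinct
causal variants (H3), one shared causal variant (H4) — with per-SNP
Wakefield approximate Bayes factors

$$\log \mathrm{ABF} = \tfrac12\Big[\log\tfrac{V}{V+W} +
   z^2\tfrac{W}{V+W}\Big],\quad V = se^2,\ W = \text{prior sd}^2 .$$

Priors are `p1 = p2 = 1e-4`, `p12 = 1e-5` per SNP, and the prior effect
SD is 0.15 for both traits — the standard default for standardized
quantitative traits; the study traits are treated as quantitative with
unit SD. All sums run in log space via log-sum-exp so |z| beyond 35
cannot overflow, and the H3 weight `S1·S2 − S12` is formed by
log-difference — with one SNP it is **exactly** zero. Since the log-ABF
is even in z, allele orientation cannot change the posteriors (asserted
in the tests, not assumed). Evidence tiers follow PP.H4: strong at
≥ 0.80, weak in [0.50, 0.80).

## Directionality, mediation, subgroups

* **Steiger**: the instrument should explain more variance in the
  protein than in the outcome. `direction_ok` iff `r²_X > r²_Y`, with a
  Fisher-z p-value. For multi-SNP sets the per-SNP variances explained
  are summed on each side and the median sample sizes used.
* **Reverse MR** swaps the trait roles through the identical machinery;
  with no genome-wide-significant outcome instruments in the region it
  returns an explicit empty result.
* **Two-step mediation**: indirect effect `a·b` by the coefficient
  product, SE by the first-order delta
  `sqrt(a²·se_b² + b²·se_a²)` with no covariance term (the two steps come
  from non-overlapping two-sample fits). The proportion mediated divides
  by the pipeline's own total-effect estimate and is reported as-is with
  a flag when outside [0, 1] or when the total is zero — a noisy total
  makes the proportion heavy-tailed, so the indirect beta is the
  quantity to trust.
* **Sex-stratified comparison**: bilateral Z-test
  `z = (β_f − β_m)/sqrt(se_f² + se_m²)`.

The pipeline's **strong-evidence tier** requires, jointly: MR
Bonferroni significance, SMR Bonferroni significance, PP.H4 ≥ 0.80,
Steiger direction support, and no HEIDI rejection. The tier is monotone:
improving any single component can never demote a protein.

## The simulator and what it does (and does not) emulate

`simulate_region()` draws summary statistics from the standard
large-sample model: with joint per-allele effects `b` on a standardized
trait, joint z-scores are `z_joint,j = b_j·sqrt(2 n f_j(1−f_j))`, and the
marginal z-scores are multivariate normal with mean `R·z_joint` and
covariance `R` (the LD correlation matrix); per-SNP standard errors are
`1/sqrt(2 n f_j(1−f_j))`. Scenarios cover a shared causal variant with
effect `theta` on the outcome, a linkage pair of distinct causal
variants at a target r², a pure null (cis-pQTL present, no outcome
effect — the stringent null for false-positive accounting), reverse
causation, a mediation chain `X → M → Y`, and sex-specific effects.

Default conditions mirror the motivating study's data: cis regions of
50 variants with AR(1) LD at ρ = 0.8 and MAF uniform on [0.05, 0.5]
(about 15% of SNPs assigned palindromic allele pairs, roughly the
genome-wide rate); a cis-pQTL per-allele effect of 0.15 SD; protein
GWAS of n = 33,000 (the per-protein effective size implied by published
F-vs-PVE pairs, rather than a consortium headline count); outcome GWAS
of n = 426,824 with sex strata of 225,000/200,000; mediator GWAS of
n = 461,460; true effect `theta = 0.3` for positive proteins. Study
bundles (`simulate_study()`) use n = 100,000 for both traits. The
mediation operating-characteristic checks use a per-allele instrument
effect of 0.5 SD (PVE ≈ 10%, matching the strong end of published
cis-pQTLs) because the chain coefficients `a = 0.02`, `b = 0.1`,
`c' = 0.03` are small and the check targets estimator calibration, not
detection power. Under `linkage`, the second causal variant sits at the
AR(1) grid point closest to the target r² (`round(log r² / 2 log ρ)`
steps), so a target of 0.5 realizes 0.41 at ρ = 0.8.

A single global seed fans out deterministically to per-trait child
streams (a Lehmer-style split), so adding a trait or protein never
perturbs another's draws and identical seeds give byte-identical
bundles.

The simulator does **not** emulate: empirical LD (block structure,
long-range LD, reference-panel error), sample overlap between the two
GWAS, binary or non-normal traits, allele-coding errors between
cohorts, population stratification, or assay-specific measurement
error. Passing the simulation suite therefore demonstrates that the
statistical machinery is correct under its stated model, not that real
datasets satisfy that model.

## Numerical choices

* p-values are floored at `1e-300`; ranking ties at the floor are broken
  by |z| (see above).
* LD matrices read from disk are symmetrized (`(M+Mᵀ)/2`), forced to
  unit diagonal, and PSD-repaired by flooring negative eigenvalues at
  zero followed by correlation renormalization (`D^{-1/2} M D^{-1/2}`),
  which preserves semi-definiteness.
* All Bayes-factor and tail-probability arithmetic runs in log space.
* Every ordering (clump acceptance, top-SNP choice, report rows:
  descending PP.H4 then ascending MR p then id) has a deterministic
  total order, so reruns are byte-identical.
* Degenerate inputs have defined behavior rather than NaN: zero exposure
  beta is an error for the Wald ratio; zero shared SNPs is an error for
  colocalization (a real situation — regions can lack overlapping
  variants); zero instruments is an explicit `no_instrument` status, not
  an omitted row.

## Validation problem sizes

The test suite and the acceptance script validate the pipeline at these
sizes, chosen to make Monte-Carlo error small relative to the bands
being checked: IVW coverage and bias over 500 shared-causal replicates
(θ = 0.1, n = 100,000, three independent instruments); colocalization
medians over 100 replicates per scenario (z ≈ 8 at the causal SNP, 50
SNPs); HEIDI size and power over 200 replicates each (30 SNPs, ρ = 0.8);
the all-null family-wise error over 20 seeds of a 50-protein screen; and
mediation calibration over 200 replicates of the full chain.

## Known limitations

* Single-variant instruments make pleiotropy diagnostics impossible at
  the per-protein level; the tier system compensates with coloc + HEIDI
  but cannot rule out pleiotropy mediated by the protein's neighbors.
* HEIDI's delta-method covariance assumes the LD matrix is oriented
  consistently with the exposure effect alleles; supplying LD from a
  mismatched reference orientation will distort it.
* The proportion mediated is a ratio of noisy estimates; its CI is not
  produced (only the indirect effect's delta CI is).
* External validation reruns forward MR only; it does not re-derive
  instruments jointly across cohorts.
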
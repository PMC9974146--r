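---
title: "Bidirectional two-sample Mendelian randomization with bimr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization with bimr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The problem and the design

Observational associations between the gut microbiome and autoimmune
disease cannot distinguish cause from consequence: a case–control study of
taxon abundances in diseased and healthy subjects is equally consistent with
the taxon promoting the disease and with the disease (or its treatment)
reshaping the microbiome. Two-sample Mendelian randomization (MR) breaks
the tie by using genetic variants as instrumental variables. Because
genotypes are fixed at conception, a variant that raises a taxon's
abundance acts like a lifelong randomized nudge to the exposure; if
carriers of that variant also show higher disease odds, the association
supports a causal path from taxon to disease. Running the analysis in both
directions — taxa as exposures against the disease, then the disease as
exposure against each taxon — probes reciprocal regulation, the situation
hypothesized for the thyroid–gut axis.

`bimr` implements the full screen over summary statistics only: per-SNP
effect sizes, standard errors, allele frequencies, and p-values from two
independent GWAS. No individual-level data are touched, and the exposure
and outcome samples are assumed non-overlapping (the two-sample
assumption).

## Instrument selection

For each exposure the selection funnel is:

1. **Significance filter.** `pvalue < p_threshold`. Default `1e-5` for
   taxa-style exposures — microbiome GWAS rarely yield genome-wide
   significant hits per taxon, and the relaxed threshold is the accepted
   convention for such panels — and genome-wide `1e-8` when the disease is
   the exposure.
2. **Frequency filter.** `min(eaf, 1 - eaf) >= maf_min`, default 0.01.
   Records with missing frequency pass (unknown, not known-bad).
3. **Greedy LD clumping.** Repeatedly take the remaining record with the
   smallest p-value as an index SNP and discard every remaining record on
   the same chromosome within `clump_window_kb` (default 500; 10,000 for
   the disease preset) whose r² with the index exceeds `clump_r2` (default
   0.01; 0.001 for the disease preset). The window is measured from the
   index SNP in both directions, the conventional semantics. SNPs missing
   from the LD reference are treated as uncorrelated.
4. **Proxy substitution.** Instruments absent from the outcome dataset are
   replaced by the outcome SNP within the reference window maximizing r²,
   provided r² > 0.8. Because the shipped LD reference stores r² only
   (signless), the proxy's outcome effect is adopted under the
   instrument's alleles assuming aligned orientation; with real reference
   panels one would use phase information here, and this is a documented
   limitation of the r²-table interface.
5. **Instrument strength.** Per-SNP variance explained is
   `2 f (1 - f) β²` on a unit-variance exposure (with a `z²/(z² + n - 2)`
   fallback when the frequency is missing); the aggregate R² is the sum
   over the retained, approximately independent instruments, and
   `F = R² (n - k - 1) / (k (1 - R²))`. A set with `F < 10` — the
   conventional weak-instrument threshold, at which instrument-variable
   bias is an appreciable fraction of the observational bias — is excluded
   as a whole. Optional per-SNP pruning at single-SNP `F < 10` is
   available (`prune_per_snp_f`) but off by default: exclusion of the set
   is the conservative action when the aggregate is weak.

The LD reference is a pluggable interface: any object answering pairwise
r² queries works, and the shipped implementation reads a tab-delimited
`(snp_a, snp_b, r2)` table such as the synthetic generator writes. No
remote panel queries are performed.

## Harmonization

Exposure and outcome effects must refer to the same effect allele per SNP.
Matching is by rsID (the datasets this design targets are rsID-keyed;
positional matching is out of scope). Identical allele pairs are kept
as-is; swapped effect/other alleles negate the outcome beta and reflect
the outcome frequency; pairs matching only after A↔T/C↔G complementation
are complemented first (a strand-reporting difference, not a biological
one). Palindromic SNPs (A/T, G/C) cannot be resolved from alleles at all,
so under the default `infer_by_eaf` policy the allele frequency is the
arbiter: the SNP is kept only when both frequencies are outside
`0.5 ± eaf_window` (default 0.08, i.e. outside [0.42, 0.58]), aligned when
they fall on the same side of 0.5 and flipped otherwise, and dropped when
either frequency is ambiguous or missing. A `drop` policy discards all
palindromic SNPs. The default window follows common two-sample MR
practice; it trades a few instruments for protection against silent sign
errors, which are catastrophic for a causal estimate.

Every input instrument ends up exactly once in the output: either as a
harmonized pair or in the dropped table with a reason
(`missing_in_outcome`, `bad_alleles`, `allele_mismatch`, `palindromic`,
`palindromic_ambiguous`) — the bookkeeping the 200-taxon screen needs to
stay auditable.

## Estimators

All multi-instrument estimators operate on the per-SNP ratio estimates
`β̂_j = Γ̂_j / γ̂_j` with first-order standard errors `SE(Γ̂_j)/|γ̂_j|` and
weights `w_j = SE(β̂_j)⁻²`. Gating by instrument count follows the
methods' own requirements: one SNP → Wald ratio; two → IVW; three adds the
weighted median and MR-Egger (with a warning at exactly three, where Egger
has a single residual degree of freedom); four adds the weighted and
simple modes.

* **IVW** is the w-weighted mean of the ratios. The default variance model
  is multiplicative random effects: the fixed-effect standard error
  `(Σ w_j)^{-1/2}` is scaled by `sqrt(max(1, Q/(k-1)))`, inflating under
  heterogeneity but never deflating — the robust default for a screen in
  which some instrument sets will be heterogeneous. A fixed-effect model
  is available.
* **MR-Egger** regresses outcome on exposure effects with a free
  intercept, weights `SE(Γ̂)⁻²`, after orienting all exposure effects
  non-negative (Egger is not invariant to allele recoding without this).
  The slope is the causal estimate; the intercept estimates the average
  directional pleiotropic effect and its t-test (k − 2 df) is the
  directional-pleiotropy diagnostic. Standard errors use multiplicative
  residual scaling floored at 1, and the closed-form weighted
  least-squares algebra is implemented directly (the tests cross-check it
  against `stats::lm`).
* **Weighted median**: the ordered ratios are interpolated at cumulative
  normalized weight 0.5 (midpoint convention `S_j − w'_j/2`), consistent
  while at least half the weight comes from valid instruments.
* **Modes**: a normal kernel is placed on each ratio with bandwidth
  `phi · 0.9 · min(sd, mad) · k^{-1/5}` (the `mad` on its consistency
  scaling; when the mad degenerates to zero with non-identical ratios the
  sd alone is used, and identical ratios return their common value
  directly). The density is evaluated on a fixed 1000-point grid spanning
  the ratio range ± 3 bandwidths and the estimate is its argmax; ties
  resolve to the smallest grid value via `which.max`. The weighted variant
  scales kernel contributions by normalized `w_j`; `phi` defaults to 1.
* **Bootstrap standard errors** for the median and modes are parametric:
  both effect sides are redrawn from `N(β̂, SE)` per SNP, the estimator is
  recomputed (including its weights), and the SE is the standard deviation
  over `n_boot` replicates (default 1000, seeded; `n_boot = 0` skips the
  bootstrap for point-estimate-only studies). P-values are normal for
  Wald/IVW/median/modes and t(k − 2) for the Egger slope and intercept.

Odds ratios are `exp(β)` with 95% bounds `exp(β ± 1.96·SE)` — the literal
1.96 convention, matching how such tables are conventionally reported.

## Sensitivity suite

* **Cochran's Q** over the ratios, `Q = Σ w_j (β̂_j − β̄)²` with the
  weighted mean `β̄`, k − 1 df; the Egger form accumulates weighted
  residuals about the Egger fit, k − 2 df. Heterogeneity is flagged at
  p < 0.05 and attached to the report; no automatic estimator switching is
  performed — the analyst sees the flag next to the estimates.
* **MR-PRESSO.** The observed residual sum of squares accumulates each
  SNP's squared outcome-SE-standardized residual from the IVW fit computed
  with that SNP left out. The null distribution is simulated (`n_sim`
  default 1000, seeded, bit-for-bit reproducible): both effect sides are
  redrawn around the leave-one-out-fitted expectations with the observed
  SEs and the statistic recomputed identically. The global p-value is the
  +1-corrected empirical tail; per-SNP outlier p-values are each SNP's
  own empirical tail, Bonferroni-corrected across the k instruments and
  flagged at 0.05. Flagged outliers are removed and the IVW estimate
  recomputed. Below four instruments the test returns a not-applicable
  result rather than an error, so pipelines report it as such. The
  distortion test of the original formulation is not run by default; the
  screen reports detection, not distortion.
* **Leave-one-out** refits the IVW estimator k times with one SNP excluded
  each. A SNP is influential when its exclusion moves the estimate outside
  the full fit's 95% interval or flips its sign. The influence flag is
  judged against the fixed-effect interval deliberately: a gross outlier
  inflates the random-effects interval in proportion to its own
  displacement, which would mask exactly the influence being probed
  (the displacement-to-interval ratio tends to 1/1.96 as the outlier
  grows, so nothing would ever be flagged).

## Pipeline and reporting

`run_direction()` drives one direction over many exposures; every exposure
ends as result rows or as a skip record with a reason (`no_instruments`,
`weak_instruments`, `all_dropped_harmonization`) — silent omission would
make a 200-taxon screen unauditable. `run_bidirectional()` composes step 1
(taxa → disease, microbiome preset) and step 2 (disease → each taxon,
genome-wide preset). Reported rows carry the odds ratio, 95% interval, and
the nominal p-value; `significant_results()` filters at α = 0.05 and sorts
by taxonomic level then p-value. Mirroring the common reporting practice
for such screens, no multiplicity correction is applied across taxa — but
a supplementary Benjamini–Hochberg column (computed within method across
exposures) is always emitted so readers can judge the screen-wide error
rate. Scatter-plot data orient each SNP so the exposure effect is
non-negative, making every estimate drawable as a slope (the Egger line
carries its intercept); rendering is left to the caller — the tested
artifact is the numbers.

All randomness flows from a single seed through deterministic sub-seed
streams, so a rerun with identical inputs and seed is byte-identical,
including the bootstrap and MR-PRESSO internals.

## The synthetic-data generator

`simulate_pair()` draws summary statistics directly from the asymptotic
sampling model rather than simulating genotypes: with effect-allele
frequency `f ~ U(maf_min, 1 − maf_min)` and sample size n, the per-allele
SE on a unit-variance trait is `(2 f (1 − f) n)^{-1/2}`, observed exposure
effects are `N(γ_j, se)`, and outcome effects are
`N(β γ_j + α_j, se_out)` with independent noise on the two sides
(non-overlapping samples by construction). Defaults emulate the study
conditions of a multi-ethnic 16S microbiome GWAS against a large biobank
disease GWAS: `n_exp = 18,340`; `n_out = 212,453` with 2,176 cases, and —
a deliberate modeling choice — the outcome SE uses the binomial effective
sample size `n_case · n_control / n_out` (≈ 2,153), the information
content of a log-odds estimate from an unbalanced case–control GWAS.
Using the raw n would make the disease dataset implausibly precise, with
consequences beyond realism: any taxon's instruments would reach
genome-wide significance in the disease GWAS and be recruited as disease
instruments, wrecking the reverse direction through reverse-causation
contamination that real unbalanced GWAS do not exhibit. Setting
`n_case = n_control = NULL` recovers the continuous-trait behavior.

Instrument effects are `γ_j ~ N(0.15, 0.03)` per SD of exposure — strong,
comfortably detectable instruments (per-SNP F in the hundreds at the
default n). Pleiotropy is configurable: `balanced` draws direct effects
centered to exact zero mean, `directional` draws `N(0.1, 0.05)`
independent of γ (InSIDE holds), and an InSIDE-violating mode correlates
α with γ for Egger stress tests. Instruments head LD blocks with AR(1)
r² decay (`rho^{2|i−j|}`, blocks 1,000 kb apart, within-block spacing
10 kb — geometry chosen to exercise the clumping window rule); tag SNPs
carry correlation-attenuated copies of the index effects so clumping has
real work to do.

`make_taxa_panel()` builds a shared-SNP-universe panel (default 20 taxa ×
2,000 SNPs — far below a real 211-taxon × 8.9M-SNP screen, scaled so the
full bidirectional suite runs in minutes) with causal structure in both
directions: a taxon's instruments propagate `effect × γ` into the disease
dataset, and 13 genome-wide-significant disease instruments
(`γ_d ~ N(0.25, 0.03)` log-odds) propagate `reverse_effect × γ_d` into
each affected taxon. In the planted validation panels the forward effect
is 0.5 and the reverse effect 0.1: a reverse effect as large as the
forward one would push the disease instruments past the taxon's `1e-5`
selection threshold (per-SNP z ≈ 6) and contaminate the forward step with
reverse-caused instruments — a failure mode real screens avoid only
because disease-on-taxon effects are modest relative to microbiome-GWAS
power. At 0.1 the disease SNPs sit near z ≈ 2 in a taxon GWAS (below
selection) while the reverse direction still detects them decisively by
combining 13 instruments.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: real allele-frequency spectra and LD
maps; winner's-curse bias from selecting instruments and estimating in the
same sample; sample overlap between exposure and outcome GWAS; population
stratification; taxon-taxon correlation; and the compositional,
zero-inflated nature of real abundance data (synthetic exposures are
continuous with unit variance, since the upstream trait transformation of
microbiome GWAS varies by consortium).

## Numerical choices and degenerate inputs

* Generated two-sided normal p-values are floored at the smallest
  normalized double, so extreme z-scores cannot underflow to an invalid
  p = 0.
* `ivw` refuses a single pair (directing the caller to the Wald ratio);
  `mr_egger` refuses exposure effects with no variation (collinear
  design); ratio estimates refuse `γ̂ = 0` exactly.
* Written summary-statistics files carry 17 significant digits so a
  write/read round trip reproduces every double bit-for-bit.
* Clumping ties in p are broken by SNP id for determinism.
* The Egger residual scale and the IVW random-effects scale are floored at
  1: heterogeneity may inflate but never deflate uncertainty.

## Validation and known limitations

The test suite validates each stage against independent oracles
(brute-force weighted mean, `stats::lm`, hand-computed cumulative-weight
interpolation, grid-search density argmax), checks the chi-square
calibration of Q, MR-PRESSO's outlier isolation and size, the
pleiotropy-robustness ordering of the estimators, and end-to-end
bidirectional discrimination with byte-identical reruns. Simulation sizes
in the shipped tests (for example 500 replicates for recovery studies,
1,000 for Q calibration, 100 for end-to-end panels) were chosen to give
tight Monte-Carlo bands while keeping the default suite in the minutes
range.

One family of checks is deliberately strict enough to fail, and the
failure is informative: at 500 replicates the Monte-Carlo error of a mean
estimate is small enough to resolve the estimators' *intrinsic*
finite-sample biases, which no correct implementation avoids. The
ratio-based estimators carry weak-instrument attenuation of order `1/F`
(measured IVW bias at β = 0.5 under the default generator: about −0.001,
matching the 1/F̄ prediction at F̄ ≈ 410); MR-Egger additionally suffers
regression-dilution attenuation of order `1 − I²_GX ≈ se_γ̂²/var(γ)`
(measured ≈ −0.026 at β = 0.5, prediction ≈ −0.034), which exceeds three
Monte-Carlo SEs at any finite instrument strength. These are properties of
the estimators, documented in the MR methods literature, not of this
implementation — the same estimators pass the exact closed-form oracle
checks at 1e-10 relative error. Users should read small systematic
attenuation toward the null as expected behavior, most pronounced for
MR-Egger with homogeneous instrument strengths.

Other limitations: no Steiger directionality filtering (instrument
selection trusts the significance asymmetry between the two GWAS); no
correlated-instrument IVW (clumping is assumed to have removed LD); no
multivariable MR; proxy substitution assumes aligned orientation (above);
and the screen's per-taxon error control is nominal by design, with the BH
column as the honest companion.
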
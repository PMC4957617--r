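---
title: "Methods: two-sample MR for the IGF axis, and what the synthetic world does and does not establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for the IGF axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

igfmr implements a single-instrument, two-sample Mendelian randomization
analysis. The causal diagram is the standard IV triangle: genotype *Z* →
exposure *X* (a circulating IGF-axis biomarker, ng/mL) → outcome *Y*
(prostate cancer risk, case-only Gleason-grade and stage contrasts, or
mortality), with unmeasured confounders allowed between *X* and *Y* but,
by the randomization-at-conception argument, not between *Z* and either.
The estimator is the ratio of the two estimable edges,

\[ \hat\beta_{\text{causal}} = \sigma_X \cdot \frac{\hat\beta_{ZY}}{\hat\beta_{ZX}}, \]

reported per one SD (\(\sigma_X\)) of the exposure. Its assumptions —
relevance, exchangeability, exclusion — map onto the three validation
operations: instrument-strength statistics, the confounder screen, and
the cross-biomarker pleiotropy matrix. The package deliberately stops at
single-SNP estimates: instruments in this region are mutually correlated
and pleiotropic across IGF peptides, so multi-SNP combination (IVW,
MR-Egger) would launder a regional signal into false precision. Estimates
from different instruments are reported side by side instead.

## Parameters that matter

* **Weak-instrument threshold, F = 10** (`f_strong`). The partial F for
  the dosage term; classification is boundary-inclusive (only F < 10 is
  weak). F relates to the incremental \(R^2\) via
  \(F = (n - 1 - k)\,R^2_{\text{partial}}/(1 - R^2_{\text{partial}})\).
* **Heterogeneity rule, p = 0.05** (`het_p`). Per-study log-ORs are
  pooled fixed-effects when Cochran's Q has p > 0.05, otherwise
  DerSimonian-Laird random-effects; the boundary p = 0.05 counts as
  evidence of heterogeneity ("no evidence" is strictly p > 0.05). I² is
  truncated at 0.
* **Confounder screen, family α = 0.05** with a configurable Bonferroni
  divisor: the number of (SNP, variable) tests is a property of the
  screen actually run, not of the package, so the divisor is exposed
  (`n_tests`).
* **HWE policy** (`hwe_flag_p = 1e-4`, `hwe_exclude_p = 0`). Variants
  failing Hardy-Weinberg are flagged, not dropped, by default — known
  HWE-violating variants still appear in published instrument tables, so
  exclusion is a pipeline decision, surfaced as a threshold. HWE is
  computed on hard-called genotypes only (|dosage − round(dosage)| < 0.1):
  on posterior dosages the test is ill-defined.
* **SD scaling** (`scale_sd`). Supplied externally, from the exposure
  sample or literature (≈ 50 ng/mL for IGF-I, ≈ 265 for IGF-II, ≈ 1000
  for IGFBP-3) — never estimated from the outcome sample, which measures
  no biomarkers.
* **Ratio-estimator SE** (`se_method`). Default `delta1`, the first-order
  delta method ignoring denominator uncertainty: reverse-engineering the
  published interval from its printed per-allele components reproduces it
  exactly under this formula, so it is the faithful default. `delta2`
  adds the denominator term; `fieller` inverts the ratio quadratic and is
  the honest choice near the weak-instrument boundary (it widens, and
  goes unbounded when the instrument cannot support the confidence
  level).

## The synthetic world

`sim_config()` fixes a complete data-generating model; the bundled
`igf_exposure_config()` / `igf_consortium_config()` encode the stated
conditions of the motivating analysis: an exposure cohort of n = 718
(the IGF-II sample), per-allele effect 94.78 ng/mL against a total SD of
265 ng/mL, and the instrument EAF 0.265 derived once from the variance
identity \(2p(1-p) = R^2\sigma^2/\beta^2\) with the published R² = 4.98%.
The consortium default is 5 studies (scaled down from 25 for test
runtime; per-study n = 400), case-control balanced, with a case-only
high-grade fraction of 0.48 and advanced-stage fraction of 0.24 (the
medians of the published per-study tables), a per-SD grade log-OR of
log(1.14), uniform censoring over a 15-year follow-up window, and an
exponential baseline hazard of 0.03/year chosen so roughly a fifth of
cases die in window. Where the source states no value (biomarker means,
IGFBP-2 log-scale parameters, confounder effects), representative
adult-male values were chosen once and are not tuned.

Mechanics worth knowing:

* **Genotypes** are sums of two latent-Gaussian haplotypes, so
  Hardy-Weinberg proportions hold exactly in expectation and pairwise LD
  targets are hit by calibrating the latent correlation against the
  bivariate-normal orthant probability (sample r² within ±0.05 at large
  n). Infeasible targets fail loudly with the Fréchet-achievable bound;
  r² = 1 duplicates the column exactly.
* **Marginal vs causal betas.** Published per-allele effects are
  *marginal* within an LD block. The bundled region therefore has one
  causal variant per block; tag SNPs acquire LD-attenuated marginal
  effects, as in real data. Stacking causal betas on correlated SNPs
  would inflate every marginal effect above its configured value.
* **Biomarkers** are linear in dosage and confounders with the Gaussian
  residual sized so the *total* SD matches the configured SD; the
  implied genetic-plus-confounder variance is validated against the
  total at construction. Log-normal biomarkers (IGFBP-2) are
  parameterised and analysed on the natural-log scale.
* **Between-study heterogeneity.** The configured τ² enters as
  per-(study, SNP) additive shifts on the genotype log-OR slope. A
  study-level intercept shift would change prevalence but leave the
  per-SNP OR — the quantity the meta-analysis pools — homogeneous, so it
  could never generate the τ² the random-effects stage is supposed to
  recover; the slope reading is the only internally consistent one.
* **Confounders never touch genotype** (the MR exchangeability
  assumption is true by construction, for positive controls), and a
  `snp_logor` switch injects a direct genotype→outcome effect (exclusion
  violated by construction, for negative controls).
* **Fixture pleiotropy.** The fixture's flagship instrument carries an
  IGFBP-3 effect at the discovery-GWAS magnitude (300 ng/mL) rather than
  the smaller exposure-cohort estimate, because the fixture must
  *guarantee* a pleiotropic strong instrument at n ≈ 700; the
  exposure-cohort value sits at expected F ≈ 7 and the first candidate
  (200 ng/mL) at a knife-edge F ≈ 11.

What the generator does **not** emulate: genotyping/imputation error
structure beyond symmetric Beta dosage noise, realistic haplotypes from
reference panels, age structure or differential PSA screening across
studies, competing risks, and informative censoring. A green test
therefore establishes the *statistical machinery* — estimator
correctness, calibration, invariances — not robustness to the
measurement pathologies of real consortium data.

## Numerical choices and degenerate inputs

Two-sided exposure p-values use the t distribution at these sample sizes;
outcome models use normal (Wald) p-values, robust when clustered. The
logistic cluster sandwich applies a g/(g−1) small-sample factor; with
singleton clusters it matches the model-based SE only asymptotically
(Hessian vs outer-product curvature), which the tests document at the 5%
level. Cox models use Breslow tie handling (ties are almost surely absent
in continuous simulated time); the proportional-hazards diagnostic is the
scaled-Schoenfeld score test with the Kaplan-Meier time transform by
default (identity and log provided — the source does not say which it
used). Perfect separation in logistic fits is reported as an error, not
an estimate; monomorphic SNPs are QC-dropped with a reason code;
all-missing vectors, zero-event survival and empty meta-analyses all fail
loudly. Meta CIs use the conventional 1.96 multiplier. Wald ratios refuse
|beta_gx| < 1e-12 and warn below the t ≈ 2 relevance rule of thumb.

## Open questions resolved here

* The exact Bonferroni divisor behind the published "p > 0.001" screen is
  unstated; 49 tests reproduce its scale, and the divisor is a parameter.
* Whether IGF-I should be adjusted for IGFBP-3 in validation regressions
  is left to the caller (any covariate set can be passed); neither mode
  is asserted as canonical.
* The published SE formula for the ratio estimator is uncited; first-order
  delta is inferred from CI arithmetic (see above) and recorded as an
  inference, with alternatives implemented.

## Known limitations

Single-instrument estimates inherit the pleiotropy of the region: the
causal claim attaches to the IGF axis, not to any one peptide. The
random-effects τ² uses the classic DL moment estimator (era-appropriate;
REML not implemented). The logistic causal OR is non-collapsible, so even
the ideal simulation recovers the per-SD log-OR only up to a small
attenuation outside the rare-outcome regime — the acceptance property
bounds this at 10% bias with 5% outcome prevalence.
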
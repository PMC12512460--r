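---
title: "Methods: paired-timepoint maternal methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-timepoint maternal methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical design of **gestewas**: what each
stage computes, the modelling assumptions behind it, the numerical choices
that affect results, and the design of the synthetic cohort generator that
stands in for array data. The worked end-to-end example lives in the README;
here the focus is on *why* the methods are what they are.

## Study design being modelled

The package analyses a small longitudinal pregnancy cohort: each woman
contributes whole-blood DNA methylation arrays at two gestational
timepoints (early pregnancy, "T1", and late-mid pregnancy, "T2"), together
with gestational age at birth (GA), maternal age, psychosocial scores and a
biomarker panel. The default synthetic design mirrors a cohort of 26 women
— 22 term births with GA between 37 and 40.5 weeks and 4 preterm births
between 32 and 36.9 weeks — with maternal age drawn from N(26.09, 4.05²).
Sample sizes this small dictate most of the robustness choices below.

## Sample pairing by SNP fingerprints

`match_samples()` re-links the two timepoints of each woman from the 59
SNP-affected probes, whose beta values cluster near 0.05 / 0.5 / 0.95 by
genotype and are stable within a person across time. Pairing maximises the
fingerprint correlation per early array and verifies mutual best matches;
ties are reported. This guards the paired analyses against plate or
labelling mix-ups without requiring genotype data.

## Cell-type deconvolution and compositional covariates

Whole-blood methylation is dominated by cell composition, so every
downstream model must account for it.

* `deconvolve()` estimates 12 leukocyte proportions per array by
  constrained least squares against a reference matrix: minimise
  ‖y − Rp‖² subject to p ≥ 0 and Σp = 1. The solver is an active-set
  method on the equality-constrained KKT system with dual-feasibility
  release; the unit tests verify the KKT certificate of optimality rather
  than comparing against a reference implementation.
* `compare_timepoints()` runs paired t-tests on the late-minus-early
  proportion differences with Bonferroni correction over the 12 cell
  types, and reports Cohen's d (= t/√n for a paired design) with the
  conventional small/medium/large labels.
* `ilr_pca()` maps proportions to isometric log-ratio (ilr) coordinates
  (zeros replaced by 1e-5 before closure), centres them robustly (median
  by default, MCD optionally), and extracts principal components. PCs 1–2
  of the ilr coordinates carry ≥ 95% of compositional variance in this
  design, and enter the regression models as the cell-composition
  covariates — **one PCA per timepoint**, since the composition shifts
  systematically between T1 and T2.

A caveat worth knowing: the ≥ 95% figure holds for the *true* (generated)
compositions. Running the same PCA on *deconvolved* proportions gives
roughly 92%, because the log-ratio transform amplifies estimation error on
rare cell types (basophils, naive B cells) into extra apparent variance
dimensions. This is a property of compositional analysis generally, not of
this implementation.

## The gestational-age EWAS

`fit_ga_ewas()` fits, per CpG and per timepoint, a robust linear model of
beta on GA, maternal age, and compositional PC1 and PC2, among the 22 term
women only (GA for preterm births is informatively censored, so non-term
arrays are dropped with a message). The estimator is Huber M-regression
(`MASS::rlm`, k = 1.345, up to 50 IRLS iterations), chosen because with
n = 22 a single contaminated array can dominate OLS. Standard errors use
the standard M-estimation sandwich-style formula, and p-values use a t
reference with df = n − 5 (arrays minus fitted coefficients).

The effect size reported is **delta-beta**: the GA coefficient times the
5th-to-95th percentile span of GA (type-7 quantiles), i.e. the predicted
methylation change across the observed GA range. A probe is significant
when BH-FDR q < 0.1 *and* |delta-beta| > 0.03.

### Empirical-null inflation correction

Adjusting by two estimated PCs does not remove all composition signal:
probes whose methylation is strongly composition-determined retain
correlated residual variation, which inflates test statistics genome-wide
(observed median t² inflation 1.3–2.2 on null simulations). `fit_ga_ewas()`
therefore recalibrates the t statistics against an empirical null
(`bacon_correct()`) before the FDR step whenever at least 200 statistics
are available; with fewer (e.g. candidate re-testing) the raw p-values are
used and `p_bacon` is `NA`. Without this correction the FDR is not
controlled; with it, the empirical false discovery proportion on fully
null cohorts stays within Monte-Carlo error of the nominal 0.1.

`bacon_correct()` is a three-component normal mixture fitted by EM to the
z-transformed statistics (t→z via log-space `pt`/`qnorm` for numerical
stability in the tails): a central null component plus two tail components
for true effects. Two identifiability constraints keep the null component
honest — tail standard deviations are bounded below by twice the null's,
and tail means are displaced at least 1.5 null-SDs from the null mean —
otherwise the tails absorb ordinary null mass and a perfectly calibrated
input comes back with null SD ≈ 0.94 instead of ≈ 1. A median/MAD fallback
covers degenerate fits, and fewer than 1000 statistics triggers a warning.

Discovery CpGs from one timepoint are re-tested at the other by
`test_candidates()`, which reports both the FDR-within-candidates call and
a relaxed nominal p < 0.01 call. `preterm_contrast()` runs Welch t-tests
term vs preterm at listed CpGs, flagging degenerate (zero-variance) probes
rather than fabricating p-values.

## The timepoint (within-woman) model

`fit_timepoint_model()` tests late-vs-early methylation change per CpG with
a woman-level random intercept, estimated by REML, with Huber robustness
weights. The variance ratio λ = τ²/σ² is profiled by one-dimensional
optimisation of the REML criterion on the log scale over [1e-8, 1e4]; the
GLS solve for all probes at once uses the Sherman–Morrison structure of the
paired design. Robustness and variance estimation alternate: profile λ,
run IRLS at fixed λ to strict tolerance (1e-8), re-profile, for at most 6
blocks within a 50-iteration budget; convergence requires the λ log-change
below 1e-3 **and** coefficient change below max(tol, 1e-6) — λ is only
located to its search tolerance, so demanding 1e-8 across blocks would
spuriously flag convergence failures. About 7% of probes fail to converge
and fall back to unweighted REML, flagged in the output. Degrees of
freedom are n_women − 1; delta-beta is the mean paired difference;
statistics pass through `bacon_correct()` and BH as above. The five
cell-type difference covariates (memory B/CD4/CD8, neutrophils, NK) absorb
composition change between timepoints.

## Surrogate scores and contribution analysis

* `il6_score()` is a weighted sum of beta values over an IL-6 CpG panel,
  reporting how many panel probes were available.
* `allostatic_load()` counts high-risk quartiles across the biomarker
  panel (sex-specific direction per marker), with cortisol adjusted for
  draw time before quartiling.
* `contribution_analysis()` quantifies mediation: for each candidate CpG,
  the GA coefficient is estimated with and without a covariate (e.g. the
  socioeconomic score), and `contribution_pct()` reports
  100 × (base − adjusted)/base. Worked check: base −0.0175 and adjusted
  −0.0128 give 26.87%.

## Co-methylated regions, mQTL flagging, chromatin states

* `build_cmrs()` chains adjacent probes on the same chromosome when the
  gap is ≤ 1000 bp and the Spearman correlation ≥ 0.3, discarding
  singletons. Tightening either knob can only shrink total membership and
  maximal chain length (the *count* of regions can rise when a region
  splits — the tests assert the well-defined monotonicities).
  `cmr_ewas()` averages member betas and reuses the GA model;
  `overlap_cmrs()` intersects region sets across timepoints.
* `count_modes()` flags probes whose beta distribution is bi- or trimodal
  (genotype-driven, mQTL-like) via kernel density mode counting with a
  separation floor, so such probes can be interpreted separately.
* `chromstate_enrichment()` computes per-state hit enrichment with
  Fisher's exact test (verified in tests against exhaustive hypergeometric
  enumeration) and the cross-product odds ratio (NA when a margin is
  zero).

## The synthetic cohort generator

`simulate_cohort()` is the package's data source and ground truth. Design
choices that matter:

* **Compositions are logistic-normal, not Dirichlet.** Two latent factors
  per woman (a granulocyte axis and a memory-cell axis) plus isotropic ilr
  jitter generate realistic correlated compositions; a Dirichlet cannot
  encode the negative granulocyte–lymphocyte covariance that drives PC1.
  This is also what makes "two PCs carry ≥ 95% of variance" true by
  construction rather than by accident.
* The timepoint composition shift is applied on the latent (pre-jitter)
  scale, so it is a within-woman systematic change, not extra noise. The
  shift vector is named by cell type and must sum to zero.
* Betas are reference × proportions plus planted effects plus
  contaminated Gaussian noise, clipped to [0, 1]; truncations are
  recorded. Planted roles (GA-associated early/late, timepoint-change,
  mediated, IL-6 panel, SNP fingerprint, co-methylated regions) are
  disjoint and fully recorded in `$truth`.
* Defaults plant 37 early and 4 late GA CpGs (slope 0.02 beta/week), 21
  timepoint CpGs (delta −0.05), and mediated CpGs whose SES-explained
  share is calibrated to 30% on the term-women GA scale.
* The manifest places region members 200 bp apart and everything else
  1500–6000 bp apart, so nothing chains across a region boundary by
  distance alone.
* Eight independent seed streams (one per component) keep every planted
  structure reproducible and the caller's RNG state untouched.

Problem sizes (5000 probes by default, 300-probe reference library) are
the package's own choice: large enough that FDR behaviour and region
construction are exercised meaningfully, small enough that the full test
suite runs in about a minute.

## Numerical conventions

All quantiles are type 7 (R's default linear interpolation); Huber
k = 1.345 (95% Gaussian efficiency); ilr zero-replacement 1e-5; EM and
IRLS tolerances as given above. These are stated because each one changes
third-decimal results if varied.

## Limitations

* n = 22 caps power; the planted-effect recovery guarantees in the test
  suite are about bias, not about single-seed detection of every probe.
* The inflation correction assumes the bulk of probes is null; it is not
  applied to small candidate sets.
* Deconvolution error propagates into the ilr PCs (see the caveat above);
  with real reference libraries the rare-cell-type amplification would be
  larger still.
* The generator's noise model is contaminated Gaussian on the beta scale,
  not an array-intensity model; preprocessing artefacts (dye bias, probe
  cross-reactivity) are out of scope.
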
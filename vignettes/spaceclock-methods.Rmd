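---
title: "Methods: longitudinal epigenetic clock analysis in small cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal epigenetic clock analysis in small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaceclock)
```

## The problem

Short-duration exposures — an orbital mission being the motivating case — may
shift DNA-methylation-based biological age estimates within days. With a
handful of subjects (here four) sampled at five timepoints (45 days before
launch, flight days 4 and 7, and 1 and 7 days after return), classical
per-biomarker inference is hopeless. The design this package implements
instead treats a *panel* of epigenetic clocks as repeated measures of the same
latent quantity: per subject and timepoint pair, the vector of per-clock
changes carries the signal, and inference is built on that vector.

`spaceclock` provides the full path from inputs (a samples × clocks estimate
table, sample metadata, and either measured cell fractions or a beta matrix
plus a deconvolution reference) to per-clock age-acceleration metrics,
per-subject significance tests, cohort-level mixed models, cell-type
attribution, and category summaries — plus a seeded synthetic-cohort
generator so every stage is testable against known ground truth.

## Metrics

For clocks expressed in years (pace-of-aging clocks are excluded from all
year-scale averaging and handled separately as raw pace deltas):

* **EAD** (epigenetic age difference): clock estimate minus chronological age.
* **EAA** (epigenetic age acceleration): the residual of an OLS regression of
  the clock estimate on chronological age and sex (coded Female = 1,
  Male = 0), fit per clock over *all* samples pooled. Pooling across subjects
  and timepoints is a deliberate choice — nothing in a 20-sample design
  supports per-timepoint fits — and the fit audit (coefficients, design rank)
  is stored in the returned object so alternative fitting windows can be
  compared.
* **IEAA** (intrinsic EAA): the residual after additionally adjusting for the
  12 predicted immune-cell fractions. Because fractions sum to one, the
  last-listed cell type is dropped from the design; residuals are invariant to
  which one is dropped (a test asserts this). Constant columns are dropped
  too, so IEAA degenerates gracefully to EAA when all compositions are equal.
  With 20 samples and up to 14 design columns the IEAA fit is near-saturated;
  the function proceeds but warns whenever residual degrees of freedom fall
  below 10. This is a real limitation of the design, not of the
  implementation: with so few residual df, IEAA absorbs part of any
  timepoint-linked signal into the cell coefficients (adjustment "toward
  zero" under collinearity), and IEAA changes should be read as conservative.

Chronological age advances across timepoints by calendar offsets divided by
365.25, because the EAA/IEAA regressions use exact decimal ages.

## Inference

Within one subject, two timepoints are compared through the vector of
per-clock paired differences:

* **Paired Wilcoxon signed-rank**, two-sided. Zeros are dropped (and
  counted), tied magnitudes are mid-ranked; the p-value is exact for n ≤ 25
  without ties and otherwise uses the normal approximation with tie and
  continuity corrections.
* **Sign-flip permutation test**: each difference is randomly assigned a
  sign, the mean recomputed, and the two-sided p is the plain proportion of
  permuted |mean|s at or above the observed |mean| (default 10,000 draws).
  No +1 smoothing is applied, so a zero exceedance count is reportable as
  "< 1/n_permutations"; the exceedance count is exposed so either convention
  can be derived. The comparison uses a 1e-8 relative tolerance on the
  observed |mean| so that the identity and sign-reversed assignments always
  count as exceedances regardless of floating-point summation order (without
  this the estimator is biased low by about 2/2^n relative to exhaustive
  enumeration).
* **Crossed random-intercept mixed model** across the cohort:
  `value ~ timepoint + (1 | subject) + (1 | clock)`, REML, fit on the two
  contrasted timepoints only (each pairwise contrast gets its own model; a
  whole-trajectory fit is available via `all_timepoints = TRUE`). P-values
  use the Satterthwaite df approximation via `lmerTest`; the method is
  recorded in the fit object. Boundary (zero) variance estimates warn rather
  than fail.
* **Leave-one-clock-out sensitivity**: the mean, Wilcoxon p and permutation p
  are recomputed with each clock removed, and rows where either p crosses
  0.05 relative to the all-clock analysis are flagged.

No multiple-testing correction is applied; all raw p-values are emitted with
comparison counts so users can correct downstream.

Confidence intervals on the mean paired difference are t-based and labelled
as such (a permutation CI is deliberately out of scope).

## Cell-type attribution by dominance analysis

Which cell types drive the gap between EAA and IEAA? The outcome
`EAA − IEAA` is stacked over (sample, clock) observations; predictors are the
sample's 12 (centred) cell fractions repeated across its clock rows — one
variance share per cell type across the whole panel. `dominance_analysis()`
enumerates all 2^12 − 1 predictor subsets, computes each subset's R² from
precomputed cross-products, and reports each predictor's *general dominance*
weight: the average over model sizes of its mean incremental R². General
dominance weights are the Shapley values of the R² set function, so they sum
to the full-model R² exactly (an identity tested to 1e-8, and against a
brute-force all-subsets `lm()` oracle to 1e-10). Conditional (per-size) and
complete (pairwise) dominance are also returned.

All 12 simplex fractions are retained as predictors: subsets where the
sum-to-one constraint binds (essentially only the full set, whose centred
columns are exactly dependent) are fit by minimum-norm least squares, whose
R² — a projection — remains well defined. One consequence worth knowing: a
cell type that *solely* drives the outcome can still receive well under 100%
of the weight, because the other 11 fractions jointly reconstruct it exactly,
so its incremental R² vanishes in large subsets. In synthetic experiments
where only the neutrophil fraction carries signal, neutrophils are always
top-ranked but their share plateaus near 50–60% even at negligible noise.
Reported shares should therefore be read as a ranking with conservative
magnitudes, not as exhaustive partitions of causality.

## Clock engine and deconvolution

`apply_linear_clock()` evaluates any user-supplied linear clock
(intercept + sparse CpG coefficients) on a beta matrix. CpGs absent from the
matrix are imputed from a user-supplied per-CpG default table (e.g.
blood-specific medians) when available, otherwise dropped; a coverage report
(found / imputed / dropped) is attached, and missingness above a configurable
fraction (default 20%) is an error. A post-transform hook exists for clocks
trained on transformed age scales; none ships enabled. Published coefficient
sets are external resources supplied by the user.

`deconvolve_cell_fractions()` estimates composition per sample by
non-negative least squares of the methylation profile on pure-cell reference
profiles, then renormalises to the simplex. NNLS-plus-renormalisation (rather
than a fully constrained QP) matches common practice for this class of
reference and keeps the solver dependency-light; per-sample NNLS residual
norms are reported, and the choice is recorded in the run manifest.
Rank-deficient references fail fast, naming the collinear columns. On
synthetic mixtures the solver is exact at zero noise and reaches per-cell
RMSE below 0.01 at beta-noise SD 0.02 — comfortably within the few-percent
error range typical of reference-based immune deconvolution.

## The synthetic cohort generator

The generator exists so that every downstream stage can be validated against
known truth without any external data. Its defaults encode the motivating
mission design; every parameter is overridable.

* **Design**: 4 subjects aged 67.7, 63.2, 31.1 and 34.6 years at launch (two
  male, two female), timepoints L-45/FD+4/FD+7/R+1/R+7 at calendar offsets
  −45, 4, 7, 10 and 16 days around a 9-day mission.
* **Clock model**: value = a_c + b_c·age + s_c·sex + u_i + v_ic + γ_c·δ_t +
  Σ_k w_ck·(π_ik − π̄_k) + ε. Year-scale slopes b_c spread deterministically
  over 0.7–1.1, intercepts and sex effects vary by clock, γ_c defaults to 1,
  residual SD defaults to 0.5 y. The pace clock is generated on its own scale
  near 1.0.
* **Random effects**: a scalar subject intercept u_i (SD 1.5 y) and a
  persistent subject-by-clock offset v_ic (SD 0.5 y), constant across
  timepoints. The latter is what gives real repeated-measures data their
  within-individual across-clock correlation; a scalar intercept alone cannot
  (Pearson centring removes it), which is why the generator carries both.
  Paired within-subject differences cancel both terms.
* **Acceleration**: δ_t is the *intrinsic* per-timepoint acceleration
  (defaults 0, +0.75, +0.22, −0.32, −0.24 y), i.e. the component that should
  survive cell adjustment. Cell-mediated acceleration enters separately:
  per-timepoint logit-scale shifts of designated cell types (defaults: small
  early-flight dips of Treg and naive CD4 fractions, a late-flight rebound
  with a neutrophil drop, post-return reversal) propagate into clocks through
  sensitivity weights w_ck (defaults concentrated on Treg, naive CD4 and
  neutrophils, scaled per clock from 0 to 2× so clocks are differentially
  cell-sensitive). Centred fractions keep δ_t and w separately identifiable.
  With these defaults the emulated cohort shows mean EAA changes of roughly
  +0.7 y at FD+4, +2 y at FD+7 and −1.5 y at R+1 with IEAA changes shrunk
  toward zero — the qualitative regime the package is designed to analyse.
* **Compositions**: Dirichlet draws (total concentration 300) around a
  realistic whole-blood immune profile (neutrophils 55%, monocytes 8%, naive
  CD4 6%, ..., Treg 1%) over a Salas-style 12-cell panel; labels are
  overridable wherever cell types appear.
* **Methylation**: `generate_methylation()` mixes pure-cell reference
  profiles by composition (plus optional Gaussian beta noise, truncated to
  [0, 1]), and `synthetic_reference()` builds a well-conditioned synthetic
  reference with cell-distinctive CpG blocks. Fixtures use hundreds of CpGs,
  not genome scale; array batch effects are out of scope.
* **Seeding**: one RNG stream per stage, derived from the master seed by
  stage name, so adding a stage never perturbs earlier draws. Identical seeds
  give byte-identical outputs end to end.

What the generator does *not* emulate: array-level technical noise structure,
probe-level QC artefacts, circadian oscillation of clock estimates,
subject-level persistence of cell composition (compositions are drawn
independently per sample around the timepoint mean), and any nonlinearity in
clock responses. Passing recovery tests on synthetic cohorts therefore
demonstrates correctness of the estimators under the stated model, not that
real mission data satisfy that model.

## Numerical choices and degenerate inputs

* Metric regressions run through one QR decomposition per design with
  multi-response residuals; rank deficiency names the collinear columns.
* Joins between tables are strict: any unmatched sample is an error, never a
  silent drop — at n = 20 a silently lost sample would visibly distort every
  downstream test.
* CSV writers emit doubles with 17 significant digits so write/read
  round-trips are exact; re-running a pipeline with the same seed reproduces
  every output byte for byte.
* Wilcoxon with no nonzero differences returns p = 1 by definition; the
  permutation test refuses empty vectors; correlation of a zero-variance
  metric vector is recorded as missing rather than erroring.
* Validation problem sizes were chosen to exercise the statistics at the
  study's own scale: 1,000 replicate null cohorts for the size of the
  permutation test, 100 seeds for parameter-recovery and attenuation checks,
  and exhaustive 2^n enumeration oracles up to n = 15.

## Known limitations

* IEAA on 20 samples has ≤ 6 residual df; its point changes are conservative
  and its significance calls fragile. The df warning is deliberate.
* The LMM treats clock panel members as exchangeable given a random
  intercept; clocks sharing training CpGs are more correlated than that, so
  cohort-level p-values are approximate (the permutation test, which
  conditions on the observed dependence, is the primary per-subject tool).
* Dominance shares under the simplex constraint are rank-reliable but
  magnitude-conservative for single-cell mechanisms (see above).
* The pipeline analyses precomputed clock estimates or linear clocks on a
  ready beta matrix; IDAT parsing, normalisation and probe QC are upstream
  concerns and out of scope.
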
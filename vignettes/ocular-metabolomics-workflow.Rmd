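---
title: "Discriminant analysis of paired ocular metabolomics: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant analysis of paired ocular metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculomet)
```

## The problem this package addresses

Targeted metabolomics panels quantify a fixed set of endogenous metabolites
(here: 188 analytes in nine classes — free carnitine, 39 acylcarnitines, the
hexose sum, 21 amino acids, 21 biogenic amines and 105 lipids) in small
animal studies with a paired design: each subject contributes a
form-deprived (FDEP) eye and a contralateral control eye, subjects are split
across two ambient-lighting groups (standard white, SW, versus blue-enriched
white, BEW), and two ocular tissues (vitreous, retina) are assayed. The
statistical questions are of two kinds:

* **independent-sample contrasts** — do lighting groups differ in their
  tissue metabolome? — addressed with OPLS-DA;
* **paired contrasts** — does the form-deprived eye differ from its fellow
  control eye? — addressed with multilevel (within-subject) PLS-DA,
  because between-subject variation would otherwise swamp the small paired
  effect.

With 14 subjects per group and ~150 usable analytes, both model families
overfit effortlessly, so the package treats validation as part of the model,
not an afterthought.

## Preprocessing

**Quantitation filter.** An analyte is excluded when *strictly more than
20%* of its values are out of quantitation range (below LLOQ, above ULOQ, or
missing); exactly 20% is retained. Fractions are computed per tissue
stratum; per-tissue analyses subset first, so one tissue's censoring cannot
delete an analyte well quantified in the other.

**Imputation.** The few below-LLOQ/missing values that survive the filter
are replaced by half the analyte's minimum quantified value — the standard
conservative rule for left-censored concentrations. Above-ULOQ values keep
their reported (capped) value when one is present.

**Transform and scaling.** Concentrations are log10-transformed
(univariate tests are defined on this scale) and columns are mean-centered
and unit-variance scaled for the multivariate models. Unit-variance scaling
is the default of the discriminant-analysis software family this workflow
emulates; it is configurable (`center`, `pareto`) because the original
choice is not documented. Unit-variance output is invariant to the log
base, so the base-10 convention is cosmetic for the multivariate stages.

## PCA screening

`pcaqc()` computes PCA by singular value decomposition (numerically exact
at this scale; the iterative NIPALS recursion is reserved for the
supervised models where deflation is intrinsic) and `hotelling_t2()` flags
samples whose score-space T2 exceeds the `A(n-1)/(n-A) F(A, n-A; 1-alpha)`
limit at `alpha = 0.05` (the conventional 95% ellipse; the original
confidence level is not documented). Flagged samples are *reported, never
removed*: exclusion is an analyst decision.

## OPLS-DA and its overfitting stack

`oplsda()` fits one predictive latent variable plus one orthogonal
component (a two-LV model, deliberately small for n = 28). The orthogonal
component is extracted by orthogonal signal correction: from the PLS weight
`w`, the loading `p` is computed and `w_o = p - (w'p)w` (normalized)
defines class-uncorrelated variation that is deflated before the final
one-component PLS fit. For a single response this training fit is exactly
equivalent to a two-component PLS model — an identity the test suite
asserts to 1e-8 — but the rotated scores separate predictive from
orthogonal variation for interpretation.

Three diagnostics guard against overfitting, and a model is accepted only
when all three pass:

1. **Cross-validated Q2** `= 1 - PRESS/SS` over K = 7 stratified folds,
   with the *entire* preprocessing (centering/scaling) re-estimated inside
   each training fold. Seven folds is the historical default of the
   software family; stratification by class prevents degenerate folds at
   n = 28. Rule: Q2 > 0.5.
2. **CV-ANOVA**: `F = ((SS - PRESS)/A) / (PRESS/(n - 1 - A))` with
   `A` total latent variables, referred to `F(A, n-1-A)`. The degrees of
   freedom follow one published parameterization; since no formula is
   canonical, validity is certified empirically — the test suite checks the
   type-I error rate stays in [0.02, 0.10] at nominal 0.05 over 500 null
   simulations at the study's dimensions (n = 28, p = 150). A model worse
   than the mean is reported as F = 0, p = 1. Rule: p < 0.05.
3. **Response permutation**: Q2 recomputed under `n_perm = 100` label
   permutations (identical fold machinery, substream-seeded). Rule: the
   median permuted Q2 is negative.

Class coding is -1/+1 with a locale-independent level order; weight signs
are fixed so the largest-magnitude element is positive, making fits
reproducible across platforms.

## Multilevel PLS-DA and resampling validation

For the paired eye contrast, `within_subject_split()` decomposes the data
matrix into subject means and within-subject deviations; the PLS-DA is fit
on the within part (two latent variables by default, in line with the
multilevel implementations in common use). Prediction of new samples
applies the same within-pair reduction, which requires complete pairs.

`validate_paired()` re-runs the whole fit on 1000 random train/test splits:
9 subject pairs (18 samples) train, 5 pairs (10 samples) test, scaling
re-estimated on training data only. The allocation unit is the *subject
pair*: training on one eye of a subject whose other eye is in the test set
would leak subject-level signal. (The naive sample-level allocation is
available as `unit = "sample"` for comparison.) Each resample records the
test AUROC (Mann-Whitney form, ties one half) and a two-sided paired t test
of the within-pair difference of predicted scores against zero. The model
family is *satisfactory* when the median AUROC is at least 0.8 and the
median p is below 0.05. Resample k draws its seed from (seed, k), so
summaries do not depend on execution order.

A property worth knowing: conditional on a *single* 14-pair dataset the
resample AUROC is a deterministic function of the allocation, so the median
over resamples retains dataset-level noise of roughly ±0.13 under the null
— no number of resamples removes it. Calibration checks of the null
therefore pool resamples over independently generated null studies (40
studies × 25 resamples in the acceptance machinery), which concentrates the
pooled median near 0.5 (observed spread about ±0.02). For a single real
dataset the median remains the right summary of *that* dataset's
validation, which is why `satisfactory` uses it unchanged.

## Univariate tests and set comparison

`univariate_tests()` runs per-analyte two-sided Student t tests on log10
concentrations — paired within subjects for the eye contrast, two-sample
(equal variance by default, Welch behind a flag) for the group contrast —
and applies Benjamini-Hochberg control at FDR 10% *within each analysis
family* (one tissue × contrast × stratum call), matching the
per-comparison framing of the study's Venn summaries; the original family
structure is not documented. Direction is the sign of the mean log
difference, so up/down matches ratio-scale fold change. `venn_compare()`
partitions two significant sets over their common universe into
condition-specific, shared-concordant and shared-discordant sets.

## The synthetic-data generator

`generate_study()` emulates the study design so that every stage is
testable without animal data:

* log10 concentration = class baseline + analyte offset (SD 0.4)
  + tissue-specific offset (SD 0.2) + subject random intercept (SD 0.15)
  + eye effect (FDEP, possibly group-dependent) + group effect (BEW)
  + residual noise (SD 0.3, i.e. ~70% concentration CV — typical for
  targeted panels);
* residuals share an exchangeable within-class correlation of 0.3, so the
  multivariate models face realistic collinearity (the true correlation
  structure of vitreous/retina is unknown; this is a modelling
  convenience);
* effects are additive on the log10 scale, multiplicative on
  concentrations, which keeps effect-size bookkeeping aligned with the
  log-scale analyses;
* censoring sets the class LLOQ at the quantile of the realized
  distribution matching the target fraction (default 5%); a designated
  block of 38 low-abundance lipid/acylcarnitine species is censored at 35%
  of its own distribution so that roughly 150 of 188 analytes survive the
  20% filter, as in the real study.

`scenario_presets()` bundles three configurations: `null` (no effects),
`paper_like` (eye effects of ~0.45 log10 units on biogenic amines and
amino acids under both lights, glycerophospholipid eye effects of opposite
sign between lights, and group effects on hexoses, lipids and amines —
chosen once to mirror the qualitative class structure of the study's
reported changes), and `strong` (1.0 log10-unit effects, ≈3.3 residual
SDs, on 15 analytes for smoke tests and parameter-recovery checks).

What the generator does *not* emulate: batch and drift effects, realistic
between-class correlation, heteroscedastic assay noise, and non-log-normal
tails. Passing tests on synthetic data certify the statistical machinery
under the declared model, not the biology of any particular dataset.

## Numerical and degenerate-input conventions

* Strict inequality at the 20% filter threshold; thresholds outside (0, 1]
  are errors.
* Zero-variance paired differences: t = 0 / p = 1 when the mean difference
  is also zero, otherwise p = 0 with a warning (degenerate separation).
* Constant columns cannot be unit-variance or pareto scaled and raise an
  error listing the columns; a concentration of 0 flagged OK is coerced to
  MISSING (log transform requires positivity).
* PLS components beyond the predictive rank raise an error rather than
  returning noise components.
* All stochastic routines (fold assignment, permutations, resampling,
  simulation) are seed-reproducible; derived substreams stay below 2^31.

## Problem sizes used by the test and acceptance machinery

Simulation-based checks run at the study's dimensions where that is cheap
(CV-ANOVA size: 500 null datasets at n = 28, p = 150; null validation:
1000 resamples pooled over 40 replicate studies; parameter recovery: 20
replicate strong-effect studies; AUROC/BH oracles: 1000 random instances
each). End-to-end pipeline tests reduce the resampling counts (150 models,
20 permutations) since the checked properties — verdict direction,
determinism, report contract — do not depend on the full-scale defaults.

## Known limitations

* The exact CV-ANOVA parameterization, fold count, scaling and
  train/test allocation of the original software are not documented, so
  printed Q2/p values of any particular historical analysis are
  reproducible only approximately.
* Multi-class contrasts, O2PLS, VIP ranking, moderated t statistics and
  batch correction are out of scope.
* The registry ships synthesized identifiers for lipid and acylcarnitine
  species (their kit-specific names are not enumerable from public
  sources); real exports can be ingested against a user-supplied registry.
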
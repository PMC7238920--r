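---
title: "Normative Mahalanobis distance scoring of white-matter tract profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative Mahalanobis distance scoring of white-matter tract profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdist)
```

## The model

`famdist` scores how unusual an individual's white-matter profile is,
considered as a whole, relative to a healthy-control population. The input
is one mean fractional anisotropy (FA) value per named tract bundle per
subject. The score is

$$M = \sqrt{(s-\mu)^\top C^{-1} (s-\mu)},$$

the Mahalanobis distance of the subject's age-residualized profile $s$ from
the control centroid $\mu$ under the control between-tract covariance $C$.
$M$ is a probability distance: all profiles on the same ellipsoidal contour
of the control density receive the same score, whatever their anatomy. That
is the point of the measure — traumatic axonal injury is spatially
heterogeneous, so a severity score should not privilege any particular
tract. The univariate comparator kept alongside is the per-tract
$|Z_t| = |s_t - \mu_t|/\mathrm{sd}_t$, which ignores covariance; comparing
the two quantifies what the covariance contributes.

Assumptions worth stating: FA residuals in controls are treated as
approximately multivariate Gaussian (the null-calibration test checks that
$M^2$ of held-out controls is $\chi^2_p$ under exactly Gaussian data); age
enters linearly; and patients are assumed to differ from controls only
through shifts, not through a different covariance structure.

## Conservative estimation in the n ≈ p regime

With p = 22 tracts and about 30 controls, the sample covariance is noisy and
its inverse amplifies that noise. Three devices make the estimate
conservative, and all three are on by default:

1. **Diagonal-target shrinkage.** $C = (1-\lambda) S + \lambda\,
   \mathrm{diag}(S)$ with the data-driven intensity $\lambda = \sum_{i\neq j}
   \widehat{\mathrm{Var}}(s_{ij}) / \sum_{i\neq j} s_{ij}^2$ (clipped to
   $[0,1]$, floored at $10^{-12}$). Only off-diagonals — the spurious
   small-sample correlations — are attenuated; variances are preserved. The
   convex combination with a positive-definite diagonal guarantees a
   positive-definite $C$ even when subsamples are smaller than p. The
   intensity is reported in every `control_model` and echoed into output
   metadata; it is an estimator property, not a scientific quantity to match
   across datasets.
2. **Permutation subsampling.** Each subject is scored against `n_perm`
   (default 1,000) random subsets of `subset_size` (default 25) controls,
   drawn without replacement; $\mu$, the per-tract SDs and $C$ are all
   re-estimated from each subset, and the subject's score is the median
   across subsets. The median is insensitive to occasional ill-conditioned
   subsets. Doubling `n_perm` beyond 1,000 changes scores by well under 2%
   (tested), so 1,000 is a converged default.
3. **Leave-one-out.** A control being scored is removed from the pool before
   subsampling, so no subject is ever compared to a reference that includes
   itself.

Numerics: quadratic forms are evaluated by Cholesky triangular solves, never
by explicit inversion; the compiled (RcppArmadillo) scoring loop is
deterministic given the permutation index matrix, which is drawn in R so
that every source of randomness flows through R's RNG. One master seed
spawns a per-subject stream keyed by a hash of the subject id, making each
subject's score independent of cohort row order; the control pool is put in
canonical id order before subsampling for the same reason.

## Design choices on points the method leaves open

* **Age model population.** The per-tract linear age regression is fit on
  controls only by default and applied to everyone: a normative model should
  not absorb patient pathology into its age slope. Fitting on all subjects is
  available (`fit_population = "all_subjects"`) and recorded in metadata.
* **|Z| denominator.** The univariate score divides by each subsample's SD,
  keeping the univariate and multivariate pipelines exactly parallel (at
  p = 1 they coincide, which the tests assert bit-for-bit). Dividing by the
  full-pool SD is available via `sd_pool = "full"`.
* **Square root.** $M$ is the classical (root) Mahalanobis distance. All
  downstream analyses (ROC, Spearman) are rank-based, so this convention is
  immaterial to them.
* **Spearman p-values.** Exact permutation enumeration below n = 10 (where
  the t approximation is poorest and enumeration is cheap), the standard
  t approximation otherwise — at the typical study n of 30–40 the
  approximation is accurate and the exact null is unaffordable.
* **Cognitive composite.** Tests whose |z skewness| or |z kurtosis| exceeds
  1.96 (either moment, two-sided) are shifted to positivity
  (`x - min(x) + 1` only when nonpositive values exist, shift recorded) and
  Box-Cox transformed with profile-ML $\lambda$ (coarse grid on $[-5,5]$,
  then golden-section refinement). All tests are standardized before PCA
  (correlation-matrix PCA), because neuropsychological tests live on
  heterogeneous scales. The first component is sign-oriented so that higher
  values mean poorer performance, using the declared per-test
  direction-of-worse; the fit uses patients only by default, since the
  composite serves as the patients' outcome variable. Both choices are
  configuration, echoed into outputs.
* **Multiple comparisons.** The 22 univariate correlations form a family and
  are BH-adjusted; the single multivariate correlation is reported
  unadjusted, because only one multivariate comparison is performed.
* **File formats.** Cohort tables are plain CSV/TSV with a header row,
  period decimal separator, UTF-8; column-to-role mapping is a small JSON
  (or in-R) schema. Result tables carry a commented `# key: value` metadata
  header with seed, permutation count, subset size and software version, and
  are written at full precision so read-back is exact.

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults encode the study conditions the package is
tested under: 31 controls, 34 patients, 22 tracts; control FA mean 0.45 and
SD 0.025 per tract (typical tract-averaged FA scales); compound-symmetry
between-tract correlation $\rho = 0.4$ — a correlated-tract regime, which is
precisely where a covariance-aware distance can outperform per-tract
z-scores; a linear age trend of −0.0008 FA/year over ages 18–60; per-patient
injury on a random 5–12 of the 22 tracts, each reduced by 0.5–1.5 control
SDs (spatially heterogeneous by construction, FA reduction by default with
signed effects supported); and a 4-test cognitive battery loaded (0.8) on
standardized total injury burden with one log-skewed test so the Box-Cox
branch always fires in end-to-end runs.

Real data differ in ways the generator deliberately ignores: between-tract
correlation is heterogeneous rather than equicorrelated; FA distributions
have mild skew and measurement artefacts; age effects can be nonlinear;
injury effects are not independent across tracts; and cognition depends on
lesion location, not only on total burden. Passing tests therefore
demonstrate that the implementation is correct and well-calibrated under its
stated model, not that the effect sizes observed on synthetic cohorts will
be observed on any real cohort.

## Problem sizes used by the test suite

The statistical property tests run at the study dimensions
(31/34/22, subset 25) with `n_perm` 200 and 100 replicate cohorts for the
discrimination property; null calibration uses a 20,000-control reference
model and 2,000 held-out draws; FDR control uses 1,000 null-cognition
replicates against one scored cohort; the composite property uses 60
replicate batteries at n = 65. These sizes give Monte-Carlo error small
enough for the stated bounds while keeping the default suite in the
low minutes on one CPU.

## Known limitations

* The diagonal-target shrinkage is tuned for stabilization, not for minimum
  Frobenius risk under every truth. When the true structure is uniformly and
  strongly equicorrelated (the generator's own default), attenuating all
  off-diagonals buys variance at a real bias cost, and per-replicate
  Frobenius improvement over the raw sample covariance is not guaranteed —
  the package's own acceptance suite measures this honestly rather than
  asserting it away. Under weaker or banded correlation the estimator
  dominates the sample covariance essentially always.
* No robust (MCD-type) covariance, no factor models, no nonlinear age
  normativity, no site/scanner harmonization, and no parametric p-value for
  M (none is defined by the method; the empirical `null_reference()`
  distribution is the supported route).
* The package begins at the per-tract FA table; all image processing
  upstream of it is out of scope.
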
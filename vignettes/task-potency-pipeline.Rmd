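---
title: "Task potency, normative deviation mapping, and out-of-sample brain-behavior CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task potency, normative deviation mapping, and out-of-sample brain-behavior CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`taskpotency` implements an individual-differences analysis of task-fMRI
functional connectivity for case-control cohorts, together with a synthetic
multi-site cohort generator that provides data with exactly the statistical
structure the analysis assumes. This vignette is the package's own account
of the model, its assumptions, the tunable parameters, and the numerical
and design choices behind the implementation.

## The model

### Task potency

Each subject contributes a resting-state scan and one or more task scans,
parcellated into R regions (default 168 regions in 11 networks). For each
scan we form a connectome in four steps:

1. **Regularized covariance** — `shrinkage_covariance()` applies
   Ledoit-Wolf shrinkage of the T x R time series' sample covariance toward
   a scaled identity target. The shrinkage intensity is estimated from the
   data (minimizing expected Frobenius risk) and recorded per subject for
   audit; the result is positive-definite even when T is comparable to R.
2. **Partial correlations** — `partial_correlation()` rescales the inverse
   covariance: `p_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`. Partial
   correlations isolate direct region-pair coupling from indirect paths.
3. **Fisher-Z** — `fisher_z()` applies `atanh` elementwise
   (variance-stabilizing). The diagonal is forced to zero before and after,
   since `atanh(1)` is undefined and self-coupling carries no information.
4. **Mixture normalization** — `fit_edge_mixture()` models each matrix's
   edge distribution as a three-component mixture: a central Gaussian (the
   null bulk of edges) plus a positive gamma above the Gaussian mean and a
   mirrored negative gamma below it (reliable signal tails).
   `normalize_connectivity()` then maps every edge to
   `(v - mu0) / sigma0` using the main Gaussian's parameters, putting each
   subject's matrix on a common scale without letting signal edges distort
   the normalization.

**Task potency** is the elementwise difference between a subject's
normalized task matrix and their normalized rest matrix
(`task_potency()`): the connectivity modulation the task induces away from
the subject's own baseline architecture. Each matrix is normalized by its
own mixture fit (rest and task separately) before subtraction.

Matrices are vectorized (`vectorize_edges()`) in a frozen edge order:
upper triangle, row-major, 0-based region indices — E = R(R-1)/2 edges,
recorded in every edge table.

### Site harmonization

Multi-site cohorts carry scanner and protocol effects.
`combat_harmonize()` applies the parametric empirical-Bayes location/scale
model per edge: standardize against the covariate-adjusted grand mean and
pooled variance, shrink per-site location (gamma) and scale (delta)
estimates toward normal / inverse-gamma priors shared across edges, adjust,
and re-add the protected covariate effects. Age, sex, and diagnostic group
are protected by default; protecting group keeps case-control differences
from being absorbed as site effects, which the downstream comparisons
depend on. Harmonization runs per task on the potency edge tables — after
potency computation, before normative modelling — so each analyzed feature
set is harmonized exactly once.

### Normative deviation

`fit_normative_model()` fits, per edge, a Bayesian linear regression of
potency on the basis `[1, age_c, age_c^2, sex]` in typically developing
(TD) subjects only (age centered on the training mean; a purely linear
basis is available by `basis = "linear"`). The quadratic term captures mild
developmental nonlinearity over the 6-30 year range while keeping a
closed-form posterior that is fast for ~14k edges x 5 tasks. Predictions
carry the coefficient-uncertainty term:

    Z = (y - yhat) / sigma_pred,   sigma_pred^2 = sigma^2 (1 + x' (X'X)^-1 x)

so subjects in sparsely sampled covariate regions are judged against wider
normative ranges, and all downstream statistics are inherently corrected
for age and sex because those effects live in `yhat`.

TD subjects are scored out of sample by 10-fold cross-validation within TD
(`td_crossval_deviations()`); autistic subjects are always scored by the
model trained on all TD subjects. A subject's global atypicality is the
percentage of edges with `|Z| > 2.571` (`atypicality_percentage()`), the
threshold nominally capturing the 1% most extreme positive and negative
values. Group differences in percent-atypical are tested per task with a
pooled-variance t test plus pooled-SD Cohen's d (`compare_groups()`;
Welch's form by `var_equal = FALSE`), with Benjamini-Hochberg correction
across the five task-level p values (`bh_fdr()`).

### Cross-task similarity

`group_mean_pattern()` averages `|Z|` per edge over a group's subjects
(absolute deviation; signed means by `absolute = FALSE`), and
`task_similarity_matrix()` correlates these patterns across tasks. The
group difference is tested with the exact Wilcoxon signed-rank test on the
T(T-1)/2 = 10 unique task-pair correlations (`compare_similarity()`); with
complete separation of the 10 pairs the exact two-sided p attains its
floor 2/2^10 ~ 0.00195.

### Brain-behavior covariation

Seven behavioral scales enter the analysis: SRS, RBS, SSP, ADHD
hyperactivity/impulsivity, ADHD inattentiveness, Vineland, and IQ; the
first five increase with impairment, the last two decrease. Missing
entries are imputed once, before cross-validation, by iterative
random-forest regression (`impute_behavior_rf()`); note the (deliberate,
order-faithful) leakage caveat: imputation sees all subjects.

The deviation table of the autistic subjects is reduced to its top 10
principal components (`reduce_dimensionality()`), and canonical
correlation analysis (`cca_fit()`, whitened cross-covariance SVD) relates
component scores to the scales. Robustness is assessed by
`crossval_cca()`: 1000 random tenfold partitions; in each fold the
reduction, standardization and CCA are refit on training folds only,
held-out subjects are projected, and their first-variate pairs are pooled
across folds into one out-of-sample correlation per split. The null is
built by `permutation_null_cca()`: behavior rows shuffled within scanner
site (preserving site structure while destroying brain-behavior coupling),
then one tenfold pass per permutation, 1000 permutations. The relationship
is declared significant when the mean of the test distribution exceeds the
95th percentile of the null (`assess_significance()`).

Loadings (`canonical_loadings()`) are structure correlations — the
correlation between each variable and its side's first canonical variate —
and edge-level brain weights come from `backproject_brain_weights()`.
Region-level profiles average `|edge value|` over the R-1 edges incident
to each region (`region_scores()`), and `top_regions()` reports the
`ceiling(0.10 * R)` highest-scoring regions (ceiling, so 168 regions give
17; ties break to the lower region index).

## The synthetic cohort generator

The generator (`sim_config()` + `generate_cohort()` /
`generate_ground_truth()` / `simulate_condition_timeseries()` /
`generate_behavior()`) emulates a multi-site autism case-control cohort:
282 autistic and 221 TD participants aged 6-30 at 6 sites, rest plus five
task conditions, 168 regions in 11 networks. Its ground truth contains
exactly the structure the analyses are meant to detect:

- a block-structured positive-definite rest precision matrix (stronger
  within-network conditional dependence);
- sparse task-specific precision modulations;
- one deviation support — a fixed edge set, identical in every task, with
  a fixed signed effect pattern — expressed only by autistic subjects,
  scaled by `deviation_amplitude * (1 + severity)` where severity is a
  latent unit-variance impairment axis (defined for all subjects, centered
  higher in autism, so behavior generation is uniform);
- per-edge age slopes, sex offsets, and per-site offsets, injected as
  task-conditional modulation so they survive the rest-subtraction that
  defines potency (harmonization and normative modelling both operate on
  potency);
- behavioral scales `direction * loading * severity + noise` with
  missing-completely-at-random masking, the pre-masking table returned as
  an oracle for imputation tests.

Deliberately **not** modelled: hemodynamics, temporal autocorrelation,
scanner drift, motion. Rows of each time series are i.i.d. multivariate
normal draws from the subject- and condition-specific precision; the
pipeline consumes only covariance structure, so this suffices to validate
every stage while keeping the full suite desk-scale. Consequently, passing
tests demonstrate statistical correctness of the pipeline under its own
assumptions, not robustness to the artifacts of real BOLD data.

A weak shared TD deviation pattern can be injected via
`td_pattern_amplitude` (default 0: unstructured TD noise), since the
empirical TD cross-task similarity is low but not exactly zero.

Two edge-level shortcuts, `simulate_potency_cohort()` and
`simulate_deviation_tables()`, generate potency edge tables and deviation
Z-tables directly from the linear normative surface, skipping the
time-series stage. They carry the same ground-truth structure (shared
signed support, severity-scaled amplitude) and power the statistical
validation at realistic subject counts in seconds. The signed (rather
than variance-inflating) deviation is essential: a linear PCA + CCA cannot
detect pure variance modulation, and the shared-pattern premise of the
cross-task analysis implies a consistent signed pattern across individuals.

## Numerical choices

- **Mixture EM**: Gaussian initialized at (median, MAD); gammas are
  anchored at the current Gaussian mean, initialized by method of moments
  on the tails beyond 2 MAD, and updated by weighted gamma MLE (Newton on
  the shape). Convergence is declared when the mean per-observation
  log-likelihood change falls below 1e-8 (the likelihood has a shallow
  ridge trading Gaussian scale against near-anchor gamma mass; a looser
  tolerance stops visibly short of the optimum), with a 2000-iteration
  cap. A fit whose main Gaussian carries <= 50% of the mass, or that fails
  to converge, falls back to robust location/scale (median, 1.4826 MAD)
  and is flagged `converged = FALSE`. At n = 14028 the recovered
  `(mu0, sigma0)` scatter a few percent around the truth along the ridge;
  recovery is therefore validated on replicate mixtures.
- **Predictive-variance floor** 1e-6 in the normative model, guarding
  against noise-free synthetic edges.
- **Threshold** 2.571 exactly as configured (the conventional two-sided 1%
  normal quantile is 2.576; the default honors the printed constant and is
  configurable).
- **PD guarantee** in the simulator: if a subject/condition perturbation
  breaks positive-definiteness, it is halved until the smallest eigenvalue
  clears 1e-6, with a message.
- **Ties** in `top_regions()` break to the ascending region index;
  the region count is `ceiling(fraction * R)`.
- **Exact Wilcoxon**: zero differences are dropped before the signed-rank
  test; the exact distribution is used up to 25 remaining pairs.
- **ComBat is nearly, not exactly, idempotent**: a second pass re-shrinks
  the sampling noise of per-site moments; its changes are an order of
  magnitude below the first pass's. This matches the reference
  implementation's behavior.

## Design choices where the design was open

- **Separate mixture fits for rest and task** matrices (each matrix
  normalized by its own fit) — normalization is a per-matrix operation.
- **Fold-wise PCA by default** in the cross-validated CCA: fitting the
  reduction inside training folds avoids leakage; `global_pca = TRUE`
  reproduces the literal one-global-reduction protocol.
- **Pooled out-of-sample correlation**: one value per split from the
  pooled held-out variate pairs, not an average of ten small-fold
  correlations — stabler for folds of ~15 subjects.
- **Sign convention on the SRS structure correlation**: each canonical
  pair is flipped so the SRS variable's correlation with the behavior
  variate is non-negative. Fixing the raw SRS weight instead can leave
  loadings pointing against the impairment axis when scales are collinear
  (weights and loadings may differ in sign); the loading convention makes
  loadings comparable across refits and interpretable along the
  impairment axis.
- **Stability is measured on loadings**, not raw weight vectors: per
  split, the mean over folds of the correlation between fold-training
  loadings and the all-data reference loadings (brain side evaluated at
  the edge level so fold-specific component spaces are comparable).
  Weights are unstable under collinearity even when the canonical mode is
  not.
- **Permutations**: 1000 permutations, each with a single tenfold pass
  (not 1000 x 1000).
- **Imputation before cross-validation** (order-faithful); the leakage
  caveat is documented above.
- **FDR family** = the five task-level p values.
- **CCA on autistic subjects only**, relating within-group variation in
  deviation patterns to behavior.

## Problem sizes used by the test suite

The suite validates the statistics at deliberately chosen desk scales:
time-series tests run at 10-40 regions and T = 60-300; null calibration of
the deviation scores uses 200-300 TD subjects and 400-5000 edges; the
case-control recovery runs 20 cohorts of 150+150 subjects with 1000 edges
and five tasks; cross-task structure recovery runs 50 seeds at 780 edges;
CCA power runs 20 cohorts of 150 autistic subjects at 276 edges with 200
splits and 200 permutations, and calibration runs 50 independent-data
seeds at 150 edges. These sizes keep each property's Monte Carlo error
well inside its assertion margin.

## Known limitations

- The BOLD model is covariance-only (no hemodynamics/autocorrelation);
  conclusions about preprocessing robustness cannot be drawn from these
  tests.
- The normative model is linear-Gaussian per edge; warped or
  Gaussian-process normative models are out of scope.
- Harmonization is the linear location/scale model (no ComBat-GAM or
  longitudinal variants); site enters the normative model only through
  upstream harmonization.
- Only the first canonical mode is tested for significance; higher modes
  are computed but not assessed.
- Group-level normative ranges treat TD as a single population, which can
  mask subgroup structure.
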
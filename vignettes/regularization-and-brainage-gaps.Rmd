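---
title: "Regularization, brain-age gaps, and disease sensitivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularization, brain-age gaps, and disease sensitivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainagegap)
```

## The problem

A brain-age model predicts chronological age from structural imaging
features; the (bias-corrected) difference between predicted and true age —
the brain-age gap — is used as a deviation score for brain health. The
conventional goal is to minimize age-prediction error, typically mean
absolute error (MAE). This package studies a competing goal: making the gap
*sensitive to disease*, quantified as the Cohen's d separating patients from
propensity-matched controls on their corrected gaps.

The central quantitative object is the ridge regularization path. With
standardized features $X$ (scaler fit on training data only), centered age
$y - \bar y$, and penalty $\alpha$, the weights solve

$$ (X^\top X + \alpha I)\, w = X^\top (y - \bar y), $$

and the prediction is $\hat y = \bar y + X w$. Sweeping $\alpha$ over a
log-spaced grid while holding everything else fixed (test pool, matched
cohorts, bias-correction procedure) exposes two distinct optima: the
$\alpha$ minimizing healthy-test MAE, and the per-condition $\alpha$
maximizing matched-cohort d. The package's headline result is that the
second sits at substantially stronger regularization than the first, with
the transition interval between them showing MAE and d rising together.

## Why the two optima separate: the generative mechanism

The synthetic cohort generator encodes the variance structure that produces
the phenomenon, so every stage is testable with known ground truth:

* **Age features** (50 by default): strong, feature-specific age slopes
  with comparatively low residual noise (SD 2.5 in raw units against
  per-year slopes of 0.05–0.15 over a 35-year age range, i.e. per-feature
  age correlations around 0.2–0.5). These are the features an
  accuracy-optimal model should use.
* **A latent global structural factor** $g$ (a total-gray-matter-volume
  analogue): declines weakly with age, carries the confounder effects, and
  is shifted in patients (in units of its SD; "global atrophy"). Age
  features load on it weakly (0.2), disease-sensitive features strongly (3).
* **Disease-sensitive features** (8): weak age trend, variance dominated by
  $g$ plus large independent noise (SD 3). Their residual (non-age) variance
  exceeds that of every age feature by construction — this ordering is
  asserted by a test.
* **Pure-noise features** (2).
* **A head-size-like factor** $h$: high cross-sectional variance (SD 1,
  loadings 0.5–1.5 on the age features), a weak *negative secular trend*
  with cohort age (older birth cohorts have smaller head size), and no
  disease response.

At small $\alpha$ the model approximates OLS: it combines the many
low-noise age features, implicitly cancels the shared factors, and the
corrected gap contains little of $g$ — accurate ages, weak disease signal.
As $\alpha$ grows, weights move toward $X^\top y$ proportions: the
disease-sensitive features' $g$ content flows into the prediction, the
corrected gap inherits the patient shift in $g$, and d rises while MAE
rises.

The head-size factor exists for a specific reason. In a purely linear
pipeline, the direction of the weight vector converges as
$\alpha \to \infty$ to the fixed direction $X^\top y$; since the corrected
gap and Cohen's d are invariant to positive rescaling of the weights, d is
then asymptotically monotone in $\alpha$, and the empirically observed
*interior* peak of the effect size could never occur. A high-variance,
age-correlated, disease-invariant component breaks this: at intermediate
$\alpha$ the $g$-direction (second-largest shared variance, strong aggregate
age covariance) dominates the gap, while at extreme $\alpha$ the head-size
direction regains relative weight in proportion to its age covariance,
injecting disease-free variance into the gap and pulling d back down. This
is also a realistic feature of imaging-derived phenotypes, where head-size
scaling pervades volumetric features and carries secular cohort trends. Set
`head_size_sd = 0` to remove it; the inversion survives, the interior peak
does not.

**Contamination.** A configurable fraction (default 5%) of undiagnosed
subjects carry a condition's feature effect without its label. They remain
in the "healthy" training pool after the split, so disease-linked variance
looks like noise with respect to age during training — mildly reinforcing
the model's preference for disease-invariant aging features.

**Confounding.** Diagnosis log-odds depend on the covariates (sex-like,
deprivation-like, one genetic-PC-like; a per-condition intercept is solved
numerically to hit the target prevalence), and the same covariates move the
global factor. Matching therefore has real work to do, and the null
scenario (all condition effects zero, confounding retained) is only clean
*after* matching — which is exactly what the null-calibration test checks.

### What the generator does not emulate

No spatial structure among features, no longitudinal trajectories, no
site/scanner effects, no non-Gaussian feature distributions, no
comorbidity structure beyond independent condition draws, and a feature
dimension of 60 rather than the ~1,400 of a full imaging-derived phenotype
battery. Passing tests therefore demonstrate that the *mechanism* produces
the phenomenon and that the pipeline measures it correctly — not that any
particular real dataset will show effects of the same size.

## Pipeline conventions

**Split.** Diagnosed subjects never enter training. The training pool is
the undiagnosed remainder minus a held-out fraction (default 30%) that
joins all patients in the test pool.

**Bias correction.** Raw gaps regress strongly on age for shrinkage
estimators. The correction is OLS of raw gap on age, fitted over *all* test
subjects (patients and controls pooled) and then frozen; analyses use the
residuals. Fitting on all test data follows the sample-level convention;
the wording is ambiguous between pooled and healthy-only fitting, so the
pooled version is the default and the healthy-only variant can be obtained
by passing only healthy rows to `fit_bias_correction()`. Residuals on the
fitting sample are zero-mean and age-orthogonal to machine precision — an
invariant asserted on every run.

**Matching.** One matched cohort per condition, built once per cohort and
reused across all models and resamples, so the model is the only varying
factor in a sweep. Propensity is a logistic model on age plus the
covariates; the caliper is 0.25 SD of the *logit* scores over the pooled
sample (the Rosenbaum–Rubin convention); matching is greedy 1:1 without
replacement in seeded random patient order. Greedy order, no-replacement,
and the logit scale are conventions, not facts of the source material; they
are deterministic given the seed, and balance diagnostics (standardized
mean differences before/after, with the pre-match pooled SD as the common
denominator) are attached to every matched cohort.

**Effect size.** Pooled-SD Cohen's d, positive = patients older-appearing;
the Hedges small-sample correction is available via a flag but off by
default. Uncertainty via within-group bootstrap (default 1,000 resamples),
with degenerate resamples redrawn and counted.

**Alpha selection.** The default CV is the exact leave-one-out shortcut:
with the design standardized once and an unpenalized intercept, the hat
diagonal $h_{ii} = 1/n + \sum_k u_{ik}^2 d_k^2/(d_k^2+\alpha)$ gives the
exact LOO residuals $e_i/(1-h_{ii})$ for the whole grid from one SVD. The
k-fold option refits the scaler inside each fold (no leakage); it is tested
against naive per-fold refitting at every grid point. CV ties break toward
larger $\alpha$ (more shrinkage, deterministic).

**Region finding.** `alpha_mae_opt` is the argmin of the mean MAE curve
(ties to larger $\alpha$); per-condition `alpha_d_opt` is the argmax of the
mean d curve (ties to smaller $\alpha$); no smoothing is applied, and SE
bands over resamples are reported so flat regions are visible.
`alpha_majority_opt` operationalizes "best for a majority of conditions" as
the $\alpha$ maximizing the number of conditions whose mean d is within one
SE of that condition's maximum (ties resolved to the median tied grid
point). The inverse-relationship flag requires the detection optimum to sit
*above* the accuracy optimum and accuracy and d to move oppositely over the
transition interval (Spearman correlation of $-$MAE and d below zero; for
intervals shorter than three grid points, the endpoint ordering).

**Attribution.** For a linear model the exact additive (Shapley)
attribution under feature independence is closed-form,
$\phi_{ij} = w_j (x_{ij} - \bar b_j)$ on the scaled space; attributions sum
per subject to prediction minus mean background prediction (asserted at
$10^{-8}$, and checked against full $2^{10}$ coalition enumeration on a
10-feature model). The background is the resample's healthy training
sample; attributions are computed on healthy test subjects. "Relative"
values in rankings are normalized by the per-$\alpha$ maximum. In sweeps
the per-feature mean |attribution| is accumulated via the identity
$\mathrm{mean}_i |\phi_{ij}| = |w_j| \cdot \mathrm{mean}_i |x^{s}_{ij}|$
(the scaled background mean is exactly zero), which a test verifies against
direct recomputation.

One subtlety worth knowing: under these defaults the shift toward global
structure at strong regularization shows in the *aggregate* attribution
mass on the disease-sensitive feature set (about 3% at the accuracy
optimum vs. 10–13% at the detection optimum), not in single-feature ranks —
no individual disease-sensitive feature outranks the strongest age
features, because the generator spreads the global factor over eight noisy
loadings rather than exposing it as one directly-measured volume.

## Numerical choices and degenerate inputs

Zero-variance features are rejected by name at scaling time. `alpha = 0`
with $p \ge n$ is refused with instructions to use a positive penalty. The
ridge path inside sweeps uses one SVD per training resample; single fits
use a dense solve of the normal equations — both are tested against an
independent dense oracle at $10^{-8}$. Constant-age samples make the bias
correction undefined and error. Zero pooled SD makes d undefined and
errors; in balance diagnostics a zero pooled SD yields an SMD of 0 with a
warning. Model JSON serialization uses 17 significant digits, which
round-trips doubles losslessly.

All randomness descends from explicit integer seeds; per-stage and
per-resample seeds are derived from one master seed so stages never share a
stream, and the full pipeline is bit-reproducible.

## Problem sizes

The default study conditions are 20,000 subjects, training resamples of
5,000 healthy subjects, a 100-point grid from $10^{-5}$ to $10^5$, 10
resamples per run, and 10 master seeds for the replicated study — small
enough to run on a laptop in a couple of minutes, large enough that the
matched cohorts for even the rarest default condition hold ~400 pairs. The
test suite uses smaller cohorts (3,000–20,000) chosen per test to keep each
check sharp.

## Known limitations

Effect sizes and MAEs here are properties of the synthetic mechanism, not
estimates for any real cohort. The matching is greedy rather than optimal;
many-to-one matching and exact matching on categorical strata are out of
scope, as are nonlinear brain-age models and their attribution. The
train-size analogue varies only the training-set size of the linear model;
training-duration and initialization effects of deep models are outside the
package's scope.
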
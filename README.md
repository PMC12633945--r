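# brainagegap

Tools for studying when brain-age models make good disease biomarkers — and
why the best age predictor is usually not the best detector.

A brain-age model predicts chronological age from structural brain features;
the bias-corrected difference between predicted and true age (the
**brain-age gap**) is used as a deviation score for brain health. This
package implements the full linear-model analysis pipeline around that idea:

* a **synthetic cohort generator** whose latent structure separates
  low-variance age-informative features from high-variance disease-sensitive
  features loading on a global structural factor (a total-gray-matter-volume
  analogue), with confounded diagnosis, optional contamination of the
  healthy training pool by undiagnosed carriers, and a hidden-truth sidecar
  for testing;
* **standard-scaled ridge regression** over a log-spaced penalty grid
  (default 100 points, 1e-5 to 1e5), with weights solving
  `(X'X + alpha I) w = X'(y - ybar)` and alpha selected by exact
  leave-one-out or k-fold cross-validation;
* **sample-level bias correction**: OLS of the raw gap on age over all test
  subjects, analyses on the residuals;
* **propensity-score matching** (logistic model, greedy 1:1 within a 0.25-SD
  logit caliper, no replacement) with balance diagnostics;
* **pooled-SD Cohen's d** of corrected gaps in matched cohorts, with
  bootstrap standard errors;
* **sweep experiments** that locate the accuracy-optimal and
  detection-optimal regularization regimes and the transition between them,
  plus a train-size analogue;
* **exact additive (Shapley) feature attributions** for the linear models,
  and the attribution-mass shift onto global features as regularization
  grows.

The headline phenomenon, reproduced end-to-end on synthetic cohorts with
known ground truth: the regularization strength that maximizes
patient–control effect sizes is orders of magnitude larger than the one that
minimizes age-prediction error, and in between the two optima MAE and
Cohen's d rise together.

## Worked example

```r
library(brainagegap)

cohort <- generate_cohort(generator_config(seed = 1))
sweep  <- run_alpha_sweep(cohort, grid = alpha_grid(), n_train = 5000,
                          n_resamples = 10, seed = 1)
identify_regions(sweep)
```

```
region_report: alpha_mae_opt = 23.1 ; alpha_majority_opt = 9770 (2 conditions)
  global_strong  alpha_d_opt = 9.77e+03 d: 0.476 -> 0.581  MAE: 3.77 -> 4.39  inverse = TRUE
  global_weak    alpha_d_opt = 4.86e+03 d: 0.180 -> 0.200  MAE: 3.77 -> 4.08  inverse = TRUE
  focal          alpha_d_opt = 1.23e+04 d: 0.128 -> 0.169  MAE: 3.77 -> 4.52  inverse = TRUE
```

Read: the most accurate model (penalty ~23, healthy-test MAE 3.77 years)
yields a matched-cohort effect size of d = 0.48 for the strong-atrophy
condition; pushing the penalty to ~1e4 costs 0.6 years of accuracy but
raises the effect size to 0.58. The `inverse = TRUE` flags mark the
transition interval where accuracy falls while detection sensitivity rises.

The numbered drivers under `analysis/` run the full sequence and write
tables under `results/analysis/`:

```sh
Rscript analysis/01_generate_cohort.R    # cohort CSV + hidden-truth sidecar
Rscript analysis/02_brainage_model.R     # CV-selected model, MAE, bias correction
Rscript analysis/03_matched_cohorts.R    # matched pairs + covariate balance
Rscript analysis/04_regularization_sweep.R
Rscript analysis/05_feature_attribution.R
Rscript analysis/06_trainsize_sweep.R
Rscript analysis/07_headline_study.R     # the three claims over 10 seeds
```

The methods vignette (`vignettes/regularization-and-brainage-gaps.Rmd`)
documents the generative mechanism, every pipeline convention, and the
design decisions.

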
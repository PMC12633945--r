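#' Build matched patient/control cohorts from a test pool
#'
#' For each condition: patients are test subjects carrying that label,
#' controls are test subjects with no condition label at all. A propensity
#' model is fitted on age plus the matching covariates and greedy 1:1 caliper
#' matching is run on the logit scores. The matched cohorts are built once per
#' cohort and reused across all models, so the model is the only factor that
#' varies in a sweep.
#'
#' @param test_cohort A `synthetic_cohort` (the test pool of [split_cohort()]).
#' @param caliper_sd Caliper in pooled logit-SD units.
#' @param seed Master seed; one match seed is derived per condition.
#' @param covariate_cols Matching covariates (default age + generator
#'   covariates present in the table).
#' @return Named list of `matched_cohort`s, one per condition, each with a
#'   `balance` data.frame attached.
#' @export
match_test_cohorts <- function(test_cohort, caliper_sd = 0.25, seed = 1,
                               covariate_cols = NULL) {
  subj <- test_cohort$subjects
  cond <- condition_columns(test_cohort)
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(c("age", covariate_names()), names(subj))
  }
  healthy <- rowSums(as.matrix(subj[cond])) == 0
  seeds <- derive_seeds(seed, length(cond))
  out <- list()
  for (i in seq_along(cond)) {
    keep <- subj[[cond[i]]] == 1 | healthy
    covs <- subj[keep, covariate_cols, drop = FALSE]
    is_pat <- subj[[cond[i]]][keep] == 1
    pm <- fit_propensity(covs, is_pat)
    mc <- match_caliper(pm$scores, is_pat, ids = subj$subject_id[keep],
                        caliper_sd = caliper_sd, seed = seeds[i])
    mc$balance <- balance_diagnostics(covs, is_pat, mc,
                                      ids = subj$subject_id[keep])
    mc$propensity <- pm
    out[[cond[i]]] <- mc
  }
  out
}

#' Regularization sweep: accuracy vs. disease-detection sensitivity
#'
#' For each of `n_resamples` training resamples (n_train subjects drawn from
#' the healthy training pool) the full ridge path over the alpha grid is fit
#' from one SVD. For every alpha, the test pool is predicted, the linear bias
#' correction is fit on all test subjects and applied, MAE is computed on the
#' healthy test subjects only, and Cohen's d of corrected gaps is computed per
#' condition on the fixed matched cohorts. Results are aggregated as mean and
#' SE over resamples. Mean absolute attributions per feature (background = the
#' resample's training sample) are accumulated alongside when
#' `attributions = TRUE`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param grid Alpha grid, default [alpha_grid()].
#' @param n_train Training subjects per resample (default 5000).
#' @param n_resamples Number of training resamples (default 10).
#' @param seed Master seed; split, matching, and per-resample seeds are
#'   derived from it.
#' @param test_fraction Held-out fraction of undiagnosed subjects.
#' @param split,matched Optional precomputed [split_cohort()] /
#'   [match_test_cohorts()] results (reused across calls).
#' @param caliper_sd Caliper for matching when `matched` is NULL.
#' @param attributions Also accumulate mean |attribution| per (alpha, feature).
#' @return A `sweep_result` with per-run tables, aggregates, the attribution
#'   table, the matched cohorts, and bookkeeping.
#' @export
run_alpha_sweep <- function(cohort, grid = alpha_grid(), n_train = 5000,
                            n_resamples = 10, seed = 1, test_fraction = 0.3,
                            split = NULL, matched = NULL, caliper_sd = 0.25,
                            attributions = TRUE) {
  stopifnot(n_resamples >= 1, length(grid) >= 1)
  seeds <- derive_seeds(seed, 2 + n_resamples)
  if (is.null(split)) split <- split_cohort(cohort, test_fraction, seed = seeds[1])
  if (is.null(matched)) {
    matched <- match_test_cohorts(split$test, caliper_sd = caliper_sd,
                                  seed = seeds[2])
  }
  pool_n <- nrow(split$train$subjects)
  if (pool_n < n_train) {
    stop("healthy training pool (", pool_n, ") smaller than n_train (",
         n_train, ")")
  }
  test <- split$test
  cond <- names(matched)
  test_ids <- test$subjects$subject_id
  test_age <- test$subjects$age
  healthy_test <- rowSums(as.matrix(test$subjects[condition_columns(test)])) == 0
  pair_rows <- lapply(matched, function(mc) {
    list(p = match(mc$pairs$patient_id, test_ids),
         c = match(mc$pairs$control_id, test_ids))
  })

  n_a <- length(grid)
  mae <- matrix(NA_real_, n_a, n_resamples)
  d_arr <- array(NA_real_, c(n_a, length(cond), n_resamples),
                 dimnames = list(NULL, cond, NULL))
  attr_sum <- if (attributions) {
    matrix(0, n_a, ncol(cohort$features),
           dimnames = list(NULL, colnames(cohort$features)))
  }

  for (r in seq_len(n_resamples)) {
    tr_idx <- withr::with_seed(seeds[2 + r], sample.int(pool_n, n_train))
    Xtr <- split$train$features[tr_idx, , drop = FALSE]
    ytr <- split$train$subjects$age[tr_idx]
    scaler <- fit_scaler(Xtr)
    Xs <- apply_scaler(scaler, Xtr)
    ybar <- mean(ytr)
    W <- ridge_path_weights(Xs, ytr - ybar, grid)     # p x n_alpha
    Xts <- apply_scaler(scaler, test$features)
    preds <- ybar + Xts %*% W                          # n_test x n_alpha
    if (attributions) {
      # background = this resample's training sample, whose scaled mean is 0,
      # so mean |phi_j| over healthy test subjects is |w_j| * mean |x_scaled_j|
      m_abs <- colMeans(abs(Xts[healthy_test, , drop = FALSE]))
      attr_sum <- attr_sum + t(abs(W) * m_abs)
    }
    for (k in seq_len(n_a)) {
      gaps <- make_gap_table(test_ids, test_age, preds[, k])
      corr <- fit_bias_correction(gaps)
      gaps <- apply_bias_correction(gaps, corr)
      mae[k, r] <- mean_absolute_error(test_age[healthy_test],
                                       preds[healthy_test, k])
      for (ci in seq_along(cond)) {
        pr <- pair_rows[[ci]]
        d_arr[k, ci, r] <- cohens_d(gaps$corrected_gap[pr$p],
                                    gaps$corrected_gap[pr$c])
      }
    }
  }

  se <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  agg_mae <- data.frame(alpha = grid,
                        mae_mean = rowMeans(mae),
                        mae_se = apply(mae, 1, se))
  agg_d <- do.call(rbind, lapply(seq_along(cond), function(ci) {
    data.frame(alpha = grid, condition = cond[ci],
               d_mean = rowMeans(d_arr[, ci, , drop = FALSE], dims = 1),
               d_se = apply(d_arr[, ci, , drop = FALSE], 1, se))
  }))
  attr_table <- if (attributions) {
    data.frame(alpha = rep(grid, ncol(attr_sum)),
               feature = rep(colnames(attr_sum), each = n_a),
               mean_abs_shap = as.vector(attr_sum / n_resamples))
  }
  structure(
    list(grid = grid, n_train = n_train, n_resamples = n_resamples,
         mae = mae, d = d_arr,
         aggregate_mae = agg_mae, aggregate_d = agg_d,
         attribution = attr_table,
         matched = matched, split = split,
         feature_roles = cohort$feature_roles,
         conditions = cond, seed = seed),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", length(x$grid), "alphas x", x$n_resamples,
      "resamples; conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  MAE range:", paste(round(range(x$aggregate_mae$mae_mean), 2),
                            collapse = " - "), "years\n")
  invisible(x)
}

#' Locate the accuracy-optimal, transition, and detection-optimal regimes
#'
#' `alpha_mae_opt` is the argmin of mean MAE (ties to larger alpha);
#' `alpha_d_opt` is the per-condition argmax of mean d (ties to smaller
#' alpha); `alpha_majority_opt` is the alpha maximizing the number of
#' conditions whose mean d lies within one SE of that condition's maximum
#' (ties to the median tied alpha). The transition interval per condition is
#' `(alpha_mae_opt, alpha_d_opt)`; the inverse-relationship flag is set when
#' prediction accuracy and detection sensitivity move in opposite directions
#' over it (Spearman correlation of -MAE and d below zero; for intervals of
#' fewer than 3 grid points, the endpoint ordering `MAE(alpha_d_opt) >
#' MAE(alpha_mae_opt)` and `d(alpha_d_opt) > d(alpha_mae_opt)`).
#'
#' @param sweep A `sweep_result`.
#' @return A `region_report`: `alpha_mae_opt`, per-condition data frame
#'   `conditions` (alpha_d_opt, d at both optima, MAE at both optima,
#'   sensitivity_gain, transition bounds, inverse_relationship), and
#'   `alpha_majority_opt`.
#' @export
identify_regions <- function(sweep) {
  grid <- sweep$grid
  mae <- sweep$aggregate_mae$mae_mean
  if (any(!is.finite(mae))) stop("non-finite MAE aggregates")
  i_mae <- max(which(mae == min(mae)))
  rows <- lapply(sweep$conditions, function(cn) {
    dsub <- sweep$aggregate_d[sweep$aggregate_d$condition == cn, ]
    dm <- dsub$d_mean
    if (any(!is.finite(dm))) stop("non-finite d aggregates for ", cn)
    i_d <- min(which(dm == max(dm)))
    lo <- min(i_mae, i_d); hi <- max(i_mae, i_d)
    # the paradox runs in the direction of increasing regularization: only a
    # detection optimum above the accuracy optimum, with accuracy and d moving
    # oppositely over the transition, counts as the inverse relationship
    inv <- if (i_d <= i_mae) {
      FALSE
    } else if (hi - lo >= 2) {
      suppressWarnings(cor(-mae[lo:hi], dm[lo:hi], method = "spearman")) < 0
    } else {
      mae[i_d] > mae[i_mae] && dm[i_d] > dm[i_mae]
    }
    data.frame(condition = cn,
               alpha_mae_opt = grid[i_mae],
               alpha_d_opt = grid[i_d],
               d_at_mae_opt = dm[i_mae],
               d_at_d_opt = dm[i_d],
               mae_at_mae_opt = mae[i_mae],
               mae_at_d_opt = mae[i_d],
               sensitivity_gain = dm[i_d] - dm[i_mae],
               transition_lo = grid[lo], transition_hi = grid[hi],
               inverse_relationship = isTRUE(inv))
  })
  cond_df <- do.call(rbind, rows)

  # majority rule: count conditions whose d(alpha) is within 1 SE of their max
  within <- vapply(sweep$conditions, function(cn) {
    dsub <- sweep$aggregate_d[sweep$aggregate_d$condition == cn, ]
    i_d <- min(which(dsub$d_mean == max(dsub$d_mean)))
    dsub$d_mean >= dsub$d_mean[i_d] - dsub$d_se[i_d]
  }, logical(length(grid)))
  counts <- rowSums(matrix(within, nrow = length(grid)))
  tied <- which(counts == max(counts))
  i_maj <- tied[ceiling(length(tied) / 2)]
  structure(
    list(alpha_mae_opt = grid[i_mae],
         conditions = cond_df,
         alpha_majority_opt = grid[i_maj],
         majority_count = max(counts)),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat("region_report: alpha_mae_opt =", signif(x$alpha_mae_opt, 3),
      "; alpha_majority_opt =", signif(x$alpha_majority_opt, 3),
      paste0("(", x$majority_count, " conditions)"), "\n")
  df <- x$conditions
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s alpha_d_opt = %-8.3g d: %.3f -> %.3f  MAE: %.2f -> %.2f  inverse = %s\n",
                df$condition[i], df$alpha_d_opt[i], df$d_at_mae_opt[i],
                df$d_at_d_opt[i], df$mae_at_mae_opt[i], df$mae_at_d_opt[i],
                df$inverse_relationship[i]))
  }
  invisible(x)
}

#' Train-size sweep
#'
#' For each training-set size, draws `n_resamples` training sets from the
#' healthy pool, selects alpha by cross-validation (policy `"cv"`) or uses a
#' fixed alpha, and reports mean and SE of healthy-test MAE and per-condition
#' matched Cohen's d.
#'
#' @param cohort A `synthetic_cohort`.
#' @param sizes Vector of training-set sizes.
#' @param alpha_policy `"cv"` or `"fixed"`.
#' @param alpha Fixed alpha (required for `alpha_policy = "fixed"`).
#' @param grid Grid for CV selection.
#' @param n_resamples Resamples per size.
#' @param seed Master seed.
#' @param test_fraction,split,matched,caliper_sd As in [run_alpha_sweep()].
#' @return Data frame: size, mae_mean, mae_se, then per condition d mean/SE in
#'   long format columns `condition`, `d_mean`, `d_se`.
#' @export
run_trainsize_sweep <- function(cohort, sizes = c(500, 1000, 2000, 5000),
                                alpha_policy = c("cv", "fixed"), alpha = NULL,
                                grid = alpha_grid(30), n_resamples = 10,
                                seed = 1, test_fraction = 0.3,
                                split = NULL, matched = NULL,
                                caliper_sd = 0.25) {
  alpha_policy <- match.arg(alpha_policy)
  if (alpha_policy == "fixed" && is.null(alpha)) {
    stop("alpha must be supplied for alpha_policy = 'fixed'")
  }
  seeds <- derive_seeds(seed, 2 + length(sizes) * n_resamples)
  if (is.null(split)) split <- split_cohort(cohort, test_fraction, seed = seeds[1])
  if (is.null(matched)) {
    matched <- match_test_cohorts(split$test, caliper_sd = caliper_sd,
                                  seed = seeds[2])
  }
  pool_n <- nrow(split$train$subjects)
  if (max(sizes) > pool_n) {
    stop("largest size (", max(sizes), ") exceeds healthy training pool (",
         pool_n, ")")
  }
  test <- split$test
  test_ids <- test$subjects$subject_id
  test_age <- test$subjects$age
  healthy_test <- rowSums(as.matrix(test$subjects[condition_columns(test)])) == 0
  cond <- names(matched)
  pair_rows <- lapply(matched, function(mc) {
    list(p = match(mc$pairs$patient_id, test_ids),
         c = match(mc$pairs$control_id, test_ids))
  })
  rows <- list()
  s_i <- 2L
  for (sz in sizes) {
    mae_r <- numeric(n_resamples)
    d_r <- matrix(NA_real_, n_resamples, length(cond),
                  dimnames = list(NULL, cond))
    alpha_r <- numeric(n_resamples)
    for (r in seq_len(n_resamples)) {
      s_i <- s_i + 1L
      tr_idx <- withr::with_seed(seeds[s_i], sample.int(pool_n, sz))
      Xtr <- split$train$features[tr_idx, , drop = FALSE]
      ytr <- split$train$subjects$age[tr_idx]
      a <- if (alpha_policy == "cv") {
        select_alpha_cv(Xtr, ytr, grid)$best_alpha
      } else {
        alpha
      }
      alpha_r[r] <- a
      model <- fit_ridge(Xtr, ytr, a)
      preds <- predict_age(model, test$features)
      gaps <- make_gap_table(test_ids, test_age, preds)
      gaps <- apply_bias_correction(gaps, fit_bias_correction(gaps))
      mae_r[r] <- mean_absolute_error(test_age[healthy_test],
                                      preds[healthy_test])
      for (ci in seq_along(cond)) {
        pr <- pair_rows[[ci]]
        d_r[r, ci] <- cohens_d(gaps$corrected_gap[pr$p],
                               gaps$corrected_gap[pr$c])
      }
    }
    se <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
    rows[[length(rows) + 1L]] <- do.call(rbind, lapply(seq_along(cond), function(ci) {
      data.frame(size = sz, condition = cond[ci],
                 mae_mean = mean(mae_r), mae_se = se(mae_r),
                 d_mean = mean(d_r[, ci]), d_se = se(d_r[, ci]),
                 alpha_median = median(alpha_r))
    }))
  }
  do.call(rbind, rows)
}
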
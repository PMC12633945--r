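#' Exact additive (Shapley) attributions for a linear model
#'
#' For a linear model under the independent-feature convention the Shapley
#' value of feature j for subject i is closed-form:
#' `phi_ij = w_j * (x_ij - mean background x_j)` on the scaled feature space.
#' Attributions per subject sum exactly to
#' `prediction_i - mean background prediction` (local accuracy).
#'
#' @param model A `ridge_model`.
#' @param samples Numeric matrix of subjects to explain.
#' @param background Numeric matrix defining the reference expectation
#'   (typically the healthy training sample).
#' @return Matrix of attributions (years), one row per sample, one column per
#'   feature.
#' @export
linear_shap <- function(model, samples, background) {
  X <- as.matrix(samples)
  B <- as.matrix(background)
  if (nrow(B) == 0L) stop("empty background")
  if (ncol(X) != length(model$weights) || ncol(B) != length(model$weights)) {
    stop("feature count mismatch with the model")
  }
  Xs <- apply_scaler(model$scaler, X)
  bg_mean <- colMeans(apply_scaler(model$scaler, B))
  phi <- sweep(Xs, 2, bg_mean)
  phi <- sweep(phi, 2, model$weights, "*")
  colnames(phi) <- model$feature_names
  phi
}

#' Rank features by mean absolute attribution
#'
#' Ranks by mean |attribution| over samples (already averaged over resamples
#' in a sweep's attribution table); ties break deterministically by feature
#' name. Relative values are normalized by the per-alpha maximum.
#'
#' @param attributions Data frame with columns `alpha`, `feature`,
#'   `mean_abs_shap` (as produced by [run_alpha_sweep()]), or a single-model
#'   attribution matrix from [linear_shap()].
#' @param k Number of top features (default 10).
#' @param alpha For the matrix form, the alpha to record.
#' @return Data frame: alpha, rank, feature, mean_abs_shap, relative.
#' @export
rank_features <- function(attributions, k = 10, alpha = 0) {
  if (is.matrix(attributions)) {
    attributions <- data.frame(alpha = alpha,
                               feature = colnames(attributions),
                               mean_abs_shap = colMeans(abs(attributions)))
  }
  stopifnot(all(c("alpha", "feature", "mean_abs_shap") %in% names(attributions)))
  out <- lapply(split(attributions, attributions$alpha), function(df) {
    if (k > nrow(df)) stop("k exceeds feature count")
    ord <- order(-df$mean_abs_shap, df$feature)
    top <- df[ord[seq_len(k)], ]
    mx <- max(df$mean_abs_shap)
    data.frame(alpha = top$alpha, rank = seq_len(k), feature = top$feature,
               mean_abs_shap = top$mean_abs_shap,
               relative = if (mx > 0) top$mean_abs_shap / mx else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$alpha, res$rank), ]
}

#' Attribution mass on global / disease-sensitive features across the grid
#'
#' The fraction of total mean |attribution| carried by a designated feature
#' set, per alpha. A rising curve means the model increasingly relies on the
#' designated (global structural) features as regularization grows.
#'
#' @param attributions Attribution table (`alpha`, `feature`,
#'   `mean_abs_shap`).
#' @param global_feature_ids Character vector of designated feature names.
#' @return Data frame: alpha, global_mass (NA with a warning where total
#'   attribution is zero).
#' @export
attribution_shift <- function(attributions, global_feature_ids) {
  stopifnot(length(global_feature_ids) >= 1)
  unknown <- setdiff(global_feature_ids, unique(attributions$feature))
  if (length(unknown)) {
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  }
  out <- lapply(split(attributions, attributions$alpha), function(df) {
    total <- sum(df$mean_abs_shap)
    gm <- if (total > 0) {
      sum(df$mean_abs_shap[df$feature %in% global_feature_ids]) / total
    } else {
      warning("total attribution is zero; global_mass undefined")
      NA_real_
    }
    data.frame(alpha = df$alpha[1], global_mass = gm)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$alpha), ]
}
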
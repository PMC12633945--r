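#' Build a brain-age gap table
#'
#' @param subject_id Subject labels.
#' @param age Chronological ages (years).
#' @param predicted_age Model predictions (years).
#' @param group Group label per subject (condition name, "control", or
#'   "healthy-test").
#' @return Data frame with `raw_gap = predicted_age - age`; `corrected_gap` is
#'   added by [apply_bias_correction()].
#' @export
make_gap_table <- function(subject_id, age, predicted_age, group = "healthy-test") {
  stopifnot(length(age) == length(predicted_age))
  data.frame(subject_id = subject_id, age = age,
             predicted_age = predicted_age,
             raw_gap = predicted_age - age,
             group = group)
}

#' Fit the sample-level linear bias correction
#'
#' Shrinkage estimators of age produce gaps that correlate negatively with age
#' (regression to the mean). The correction is an ordinary least squares fit of
#' the raw gap on age over all supplied test rows — patients and controls
#' together by default — whose residuals are the corrected gaps.
#'
#' @param gaps Gap table from [make_gap_table()] (needs `age`, `raw_gap`).
#' @return A `bias_correction`: slope (dimensionless), intercept (years),
#'   n_fit.
#' @export
fit_bias_correction <- function(gaps) {
  stopifnot(is.data.frame(gaps), all(c("age", "raw_gap") %in% names(gaps)))
  if (nrow(gaps) < 3) stop("need at least 3 rows to fit the bias correction")
  if (sd(gaps$age) == 0) stop("age is constant; bias correction undefined")
  b <- lm.fit(cbind(intercept = 1, age = gaps$age), gaps$raw_gap)$coefficients
  structure(list(slope = unname(b["age"]), intercept = unname(b["intercept"]),
                 n_fit = nrow(gaps)),
            class = "bias_correction")
}

#' @export
print.bias_correction <- function(x, ...) {
  cat("bias_correction: gap ~ ", round(x$intercept, 3), " + ",
      round(x$slope, 4), " * age  (n = ", x$n_fit, ")\n", sep = "")
  invisible(x)
}

#' Apply a fitted bias correction
#'
#' `corrected_gap = raw_gap - (slope * age + intercept)`. On the fitting
#' sample the corrected gaps have zero mean and zero age correlation to
#' numerical precision (OLS residual orthogonality).
#'
#' @param gaps Gap table.
#' @param corr A `bias_correction`.
#' @return The gap table with a `corrected_gap` column.
#' @export
apply_bias_correction <- function(gaps, corr) {
  stopifnot(inherits(corr, "bias_correction"))
  gaps$corrected_gap <- gaps$raw_gap - (corr$slope * gaps$age + corr$intercept)
  gaps
}
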
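#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_patients - mean_controls) / pooled SD`, with
#' `pooled SD = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` using
#' sample variances. Sign convention: positive d means patients have larger
#' (older-appearing) corrected brain-age gaps. An optional small-sample
#' (Hedges) correction multiplies by `1 - 3/(4 (n1 + n2) - 9)`.
#'
#' @param gaps_patients,gaps_controls Numeric vectors, each of length >= 2.
#' @param hedges Apply the small-sample correction (default `FALSE`).
#' @return Cohen's d (dimensionless).
#' @export
cohens_d <- function(gaps_patients, gaps_controls, hedges = FALSE) {
  n1 <- length(gaps_patients); n2 <- length(gaps_controls)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  pooled <- sqrt(((n1 - 1) * var(gaps_patients) +
                    (n2 - 1) * var(gaps_controls)) / (n1 + n2 - 2))
  if (!(pooled > 0)) stop("zero pooled SD; Cohen's d undefined")
  d <- (mean(gaps_patients) - mean(gaps_controls)) / pooled
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  d
}

#' Bootstrap standard error of Cohen's d
#'
#' Resamples with replacement within each group, recomputes d, and reports the
#' SD over resamples. Degenerate resamples (zero pooled SD) are redrawn and
#' counted.
#'
#' @param gaps_patients,gaps_controls Numeric vectors.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return Bootstrap SE, with attribute `n_redrawn` counting redraws.
#' @export
bootstrap_se <- function(gaps_patients, gaps_controls, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  n1 <- length(gaps_patients); n2 <- length(gaps_controls)
  withr::with_seed(as.integer(seed), {
    ds <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        xb <- gaps_patients[sample.int(n1, n1, replace = TRUE)]
        yb <- gaps_controls[sample.int(n2, n2, replace = TRUE)]
        d <- tryCatch(cohens_d(xb, yb), error = function(e) NA_real_)
        if (!is.na(d)) break
        redrawn <- redrawn + 1L
      }
      ds[b] <- d
    }
    structure(sd(ds), n_redrawn = redrawn)
  })
}

#' Effect size of a matched patient/control comparison
#'
#' Convenience wrapper combining [cohens_d()] and [bootstrap_se()] over the
#' corrected gaps of a matched cohort.
#'
#' @param gaps Gap table with `subject_id` and `corrected_gap`.
#' @param matched A `matched_cohort`.
#' @param condition Condition label to record.
#' @param n_boot,seed Passed to [bootstrap_se()]; `n_boot = 0` skips the SE.
#' @return One-row data frame: condition, d, se, n_pairs.
#' @export
matched_effect_size <- function(gaps, matched, condition = "condition",
                                n_boot = 1000, seed = 1) {
  gp <- gaps$corrected_gap[match(matched$pairs$patient_id, gaps$subject_id)]
  gc <- gaps$corrected_gap[match(matched$pairs$control_id, gaps$subject_id)]
  if (anyNA(gp) || anyNA(gc)) stop("matched ids missing from the gap table")
  d <- cohens_d(gp, gc)
  se <- if (n_boot > 0) as.numeric(bootstrap_se(gp, gc, n_boot, seed)) else NA_real_
  data.frame(condition = condition, d = d, se = se,
             n_pairs = matched$n_pairs,
             sign_convention = "positive = patients older-appearing")
}
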
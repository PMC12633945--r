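#' Fit a propensity score model
#'
#' Logistic regression of patient status on the matching covariates; scores
#' are returned on the logit scale, the scale on which the caliper is defined.
#'
#' @param covariates Data frame of matching covariates (no missing values).
#' @param is_patient Binary/logical vector, `TRUE`/1 = patient.
#' @return A `propensity_model` with `coefficients`, `intercept`, `scores`
#'   (logit) for the supplied rows, and `converged`.
#' @export
fit_propensity <- function(covariates, is_patient) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(is_patient))
  y <- as.integer(is_patient)
  if (length(unique(y)) < 2) stop("both patients and controls are required")
  if (anyNA(covariates)) stop("missing values in covariates")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = cbind(y = y, covariates), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  probs <- fitted(fit)
  if (any(probs < 1e-10 | probs > 1 - 1e-10)) separation <- TRUE
  if (separation || !fit$converged) {
    stop("propensity model did not converge (possible perfect separation); ",
         "consider exact matching without a caliper or a penalized fit")
  }
  cf <- coef(fit)
  structure(
    list(coefficients = cf[-1], intercept = unname(cf[1]),
         score_scale = "logit",
         scores = unname(predict(fit, type = "link")),
         converged = fit$converged,
         covariate_names = names(covariates)),
    class = "propensity_model"
  )
}

#' Score new subjects on the logit propensity scale
#'
#' @param model A `propensity_model`.
#' @param covariates Data frame with the model's covariate columns.
#' @return Numeric logit scores.
#' @export
propensity_scores <- function(model, covariates) {
  X <- as.matrix(covariates[, model$covariate_names, drop = FALSE])
  drop(model$intercept + X %*% model$coefficients)
}

#' Greedy 1:1 caliper matching on the propensity score
#'
#' The caliper width is `caliper_sd` times the SD of the scores over the
#' pooled sample (the Rosenbaum-Rubin convention on the logit scale). Patients
#' are visited in seeded random order; each takes its nearest unused control
#' within the caliper, without replacement. Patients with no in-caliper
#' control left are reported unmatched.
#'
#' @param scores Numeric propensity scores (logit scale unless
#'   `caliper_scale = "probability"`, in which case supply probabilities).
#' @param is_patient Binary/logical vector aligned with `scores`.
#' @param ids Optional subject ids aligned with `scores`; defaults to indices.
#' @param caliper_sd Caliper in pooled-score SD units (default 0.25).
#' @param seed Seed for the patient visiting order.
#' @param caliper_scale Label recorded alongside the caliper; scores are used
#'   as given.
#' @return A `matched_cohort`: `pairs` (patient_id, control_id, distance),
#'   `caliper_width`, `unmatched_patients`, `n_pairs`.
#' @export
match_caliper <- function(scores, is_patient, ids = NULL,
                          caliper_sd = 0.25, seed = 1,
                          caliper_scale = "logit") {
  stopifnot(length(scores) == length(is_patient), caliper_sd > 0)
  if (is.null(ids)) ids <- seq_along(scores)
  pat <- which(as.logical(is_patient))
  ctl <- which(!as.logical(is_patient))
  if (length(ctl) == 0L) stop("no controls available for matching")
  if (length(pat) == 0L) stop("no patients to match")
  width <- caliper_sd * sd(scores)
  order_pat <- withr::with_seed(as.integer(seed), sample(pat))
  cs <- scores[ctl]
  used <- rep(FALSE, length(ctl))
  p_id <- character(0); c_id <- character(0); dist <- numeric(0)
  unmatched <- character(0)
  for (i in order_pat) {
    d <- abs(cs - scores[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= width) {
      used[j] <- TRUE
      p_id <- c(p_id, as.character(ids[i]))
      c_id <- c(c_id, as.character(ids[ctl[j]]))
      dist <- c(dist, d[j])
    } else {
      unmatched <- c(unmatched, as.character(ids[i]))
    }
  }
  structure(
    list(pairs = data.frame(patient_id = p_id, control_id = c_id,
                            distance = dist),
         caliper_width = width, caliper_sd = caliper_sd,
         caliper_scale = caliper_scale,
         unmatched_patients = unmatched,
         n_pairs = length(p_id)),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", x$n_pairs, "pairs,",
      length(x$unmatched_patients), "unmatched patients, caliper width",
      signif(x$caliper_width, 4), paste0("(", x$caliper_scale, ")"), "\n")
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference per covariate:
#' `(mean_patient - mean_control) / pooled SD`, with the pooled SD taken from
#' the pre-match groups for both rows so before/after are on a common scale.
#'
#' @param covariates Data frame of covariates for all subjects.
#' @param is_patient Binary/logical vector aligned with `covariates`.
#' @param matched A `matched_cohort` whose ids index into `ids`.
#' @param ids Subject ids aligned with `covariates` (default indices).
#' @return Data frame: covariate, smd_before, smd_after.
#' @export
balance_diagnostics <- function(covariates, is_patient, matched,
                                ids = NULL) {
  if (is.null(ids)) ids <- seq_len(nrow(covariates))
  ids <- as.character(ids)
  if (matched$n_pairs < 1) stop("need at least one matched pair")
  pat <- as.logical(is_patient)
  rows_p <- match(matched$pairs$patient_id, ids)
  rows_c <- match(matched$pairs$control_id, ids)
  smd <- function(rows1, rows2, x, pooled_sd) {
    if (pooled_sd == 0) {
      warning("zero pooled SD; SMD reported as 0")
      return(0)
    }
    (mean(x[rows1]) - mean(x[rows2])) / pooled_sd
  }
  out <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    n1 <- sum(pat); n2 <- sum(!pat)
    ps <- sqrt(((n1 - 1) * var(x[pat]) + (n2 - 1) * var(x[!pat])) /
                 (n1 + n2 - 2))
    data.frame(covariate = nm,
               smd_before = smd(which(pat), which(!pat), x, ps),
               smd_after = smd(rows_p, rows_c, x, ps))
  })
  do.call(rbind, out)
}
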
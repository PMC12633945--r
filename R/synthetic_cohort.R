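#' Specify a condition for the synthetic cohort
#'
#' A condition is a binary diagnosis with a target prevalence, an effect on the
#' latent global structural factor (in units of that factor's SD, negative =
#' atrophy-like), optional focal effects on individual disease-sensitive
#' features (raw feature units), and a scaling of how strongly the shared
#' confounders drive its diagnosis log-odds.
#'
#' @param name Condition label (used as a column name, so must be a valid name).
#' @param prevalence Target marginal prevalence, in (0, 0.5).
#' @param global_shift Case effect on the global factor, in global-factor SD
#'   units. Negative values mimic global atrophy.
#' @param focal_shifts Numeric vector of per-feature case effects on the
#'   disease-sensitive features (raw units). Recycled with zeros to the number
#'   of disease features at generation time; `NULL` means no focal effect.
#' @param confounding_strength Multiplier on the covariate-to-diagnosis
#'   log-odds effects (0 = diagnosis independent of covariates).
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(name, prevalence, global_shift = 0,
                           focal_shifts = NULL, confounding_strength = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 0.5) {
    stop("condition '", name, "': prevalence must lie in (0, 0.5)")
  }
  if (!is.null(focal_shifts) && !is.numeric(focal_shifts)) {
    stop("condition '", name, "': focal_shifts must be numeric or NULL")
  }
  structure(
    list(name = name, prevalence = prevalence, global_shift = global_shift,
         focal_shifts = focal_shifts,
         confounding_strength = confounding_strength),
    class = "condition_spec"
  )
}

#' Default condition set
#'
#' Three conditions spanning the qualitative variety of patient groups: a rare
#' condition with a strong global (atrophy-like) effect, a commoner condition
#' with a weak global effect, and a condition with purely focal effects on
#' three disease-sensitive features.
#'
#' @return List of [condition_spec()] objects.
#' @export
default_conditions <- function() {
  list(
    condition_spec("global_strong", prevalence = 0.02, global_shift = -1.0),
    condition_spec("global_weak", prevalence = 0.05, global_shift = -0.5),
    condition_spec("focal", prevalence = 0.03,
                   focal_shifts = c(-2, -2, -2))
  )
}

#' Default covariate specification
#'
#' Confounders shared by all conditions: a sex-like binary, an SES-like
#' continuous score, a deprivation-like continuous score, and three genetic-PC
#' style continuous scores. `diagnosis_log_odds` gives each covariate's effect
#' on every condition's diagnosis log-odds (scaled per condition by its
#' `confounding_strength`); `global_factor_effects` gives each covariate's
#' effect on the latent global structural factor, which is how confounding
#' reaches the features.
#'
#' @return A list with elements `diagnosis_log_odds` and
#'   `global_factor_effects`, both named numeric vectors over the covariates.
#' @export
covariate_spec <- function() {
  covars <- c("sex", "ses", "deprivation", "pc1", "pc2", "pc3")
  list(
    diagnosis_log_odds = setNames(c(0.3, 0, 0.5, 0.1, 0, 0), covars),
    global_factor_effects = setNames(c(0.4, 0.1, -0.15, 0, 0, 0), covars)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' The generator encodes the variance structure under which accuracy-optimal
#' and detection-optimal regularization regimes separate: age-informative
#' features with low residual variance, disease-sensitive features whose
#' cross-sectional variance is dominated by a latent global structural factor
#' (a total-gray-matter-volume analogue), pure-noise features, and a
#' high-variance disease-insensitive head-size-like factor with a weak secular
#' (birth-cohort) age trend.
#'
#' @param n_subjects Number of subjects.
#' @param age_min,age_max Age range in years; ages are uniform on it.
#' @param n_age_features,n_disease_features,n_noise_features Feature counts.
#' @param age_loadings Slope of each age feature on age (units/year). Default
#'   `seq(-0.15, -0.05, length.out = n_age_features)`, volumes shrinking with
#'   age.
#' @param global_factor_sd Cross-sectional SD of the global factor's intrinsic
#'   noise; condition `global_shift`s are expressed in this unit.
#' @param global_age_slope Slope of the global factor on centered age
#'   (units/year); negative = global decline with age.
#' @param age_feature_g_loading Loading of each age feature on the global
#'   factor (small by construction).
#' @param disease_age_slope Weak slope of disease features on age (units/year).
#' @param disease_feature_g_loading Loading of disease features on the global
#'   factor (large by construction).
#' @param head_size_sd SD of the head-size-like factor; `0` removes it.
#' @param head_size_age_slope Secular cohort trend of the head-size factor on
#'   centered age (units/year).
#' @param head_size_loadings Loadings of the age features on the head-size
#'   factor; default `seq(0.5, 1.5, length.out = n_age_features)`.
#' @param age_feature_noise_sd,disease_feature_noise_sd,noise_feature_sd
#'   Independent noise SDs; `age_feature_noise_sd < disease_feature_noise_sd`
#'   is enforced (the mechanism requires it).
#' @param conditions List of [condition_spec()]; default [default_conditions()].
#' @param covariates Covariate spec as from [covariate_spec()].
#' @param contamination_rate Fraction of undiagnosed subjects carrying an
#'   (unlabeled) disease effect, in `[0, 1)`.
#' @param seed Integer seed making generation deterministic.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_subjects = 20000,
                             age_min = 45, age_max = 80,
                             n_age_features = 50,
                             n_disease_features = 8,
                             n_noise_features = 2,
                             age_loadings = NULL,
                             global_factor_sd = 1,
                             global_age_slope = -0.03,
                             age_feature_g_loading = 0.2,
                             disease_age_slope = -0.1,
                             disease_feature_g_loading = 3,
                             head_size_sd = 1,
                             head_size_age_slope = -0.02,
                             head_size_loadings = NULL,
                             age_feature_noise_sd = 2.5,
                             disease_feature_noise_sd = 3,
                             noise_feature_sd = 3,
                             conditions = default_conditions(),
                             covariates = covariate_spec(),
                             contamination_rate = 0.05,
                             seed = 1) {
  if (is.null(age_loadings)) {
    age_loadings <- seq(-0.15, -0.05, length.out = n_age_features)
  }
  if (is.null(head_size_loadings)) {
    head_size_loadings <- seq(0.5, 1.5, length.out = n_age_features)
  }
  cfg <- structure(
    list(n_subjects = n_subjects, age_min = age_min, age_max = age_max,
         n_age_features = n_age_features,
         n_disease_features = n_disease_features,
         n_noise_features = n_noise_features,
         age_loadings = age_loadings,
         global_factor_sd = global_factor_sd,
         global_age_slope = global_age_slope,
         age_feature_g_loading = age_feature_g_loading,
         disease_age_slope = disease_age_slope,
         disease_feature_g_loading = disease_feature_g_loading,
         head_size_sd = head_size_sd,
         head_size_age_slope = head_size_age_slope,
         head_size_loadings = head_size_loadings,
         age_feature_noise_sd = age_feature_noise_sd,
         disease_feature_noise_sd = disease_feature_noise_sd,
         noise_feature_sd = noise_feature_sd,
         conditions = conditions,
         covariates = covariates,
         contamination_rate = contamination_rate,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  must <- function(ok, what) if (!isTRUE(ok)) stop("invalid generator_config: ", what)
  must(cfg$n_subjects > 0, "n_subjects must be > 0")
  must(cfg$n_age_features > 0, "n_age_features must be > 0")
  must(cfg$n_disease_features > 0, "n_disease_features must be > 0")
  must(cfg$n_noise_features >= 0, "n_noise_features must be >= 0")
  must(cfg$age_min < cfg$age_max, "age_min must be < age_max")
  must(length(cfg$age_loadings) == cfg$n_age_features,
       "age_loadings length must equal n_age_features")
  must(length(cfg$head_size_loadings) == cfg$n_age_features,
       "head_size_loadings length must equal n_age_features")
  must(cfg$global_factor_sd > 0, "global_factor_sd must be > 0")
  must(cfg$age_feature_noise_sd > 0, "age_feature_noise_sd must be > 0")
  must(cfg$disease_feature_noise_sd > 0, "disease_feature_noise_sd must be > 0")
  must(cfg$noise_feature_sd > 0, "noise_feature_sd must be > 0")
  must(cfg$age_feature_noise_sd < cfg$disease_feature_noise_sd,
       "age_feature_noise_sd must be < disease_feature_noise_sd")
  must(cfg$head_size_sd >= 0, "head_size_sd must be >= 0")
  must(cfg$contamination_rate >= 0 && cfg$contamination_rate < 1,
       "contamination_rate must lie in [0, 1)")
  must(length(cfg$conditions) >= 1, "at least one condition is required")
  for (cc in cfg$conditions) {
    must(inherits(cc, "condition_spec"), "conditions must be condition_spec objects")
    if (!is.null(cc$focal_shifts)) {
      must(length(cc$focal_shifts) <= cfg$n_disease_features,
           paste0("condition '", cc$name,
                  "': focal_shifts longer than n_disease_features"))
    }
  }
  nms <- vapply(cfg$conditions, `[[`, "", "name")
  must(!anyDuplicated(nms), "condition names must be unique")
  invisible(cfg)
}

covariate_names <- function() c("sex", "ses", "deprivation", "pc1", "pc2", "pc3")

# Intercept of the diagnosis logistic model solved so that the marginal
# prevalence over the sampled covariates hits its target.
calibrate_intercept <- function(eta, prevalence) {
  uniroot(function(b0) mean(plogis(b0 + eta)) - prevalence,
          interval = c(-30, 10), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly, samples confounders, assigns each condition from a
#' logistic model on the confounders with a prevalence-calibrated intercept,
#' builds the latent global and head-size factors, and emits the feature
#' matrix: age features (strong age slope, small global-factor loading,
#' head-size loading, low noise), disease features (weak age slope, strong
#' global-factor loading, focal case shifts, high noise), and pure-noise
#' features. A `contamination_rate` fraction of undiagnosed subjects carry the
#' feature-level effect of a (prevalence-weighted) condition without its label.
#' Ground truth (latent factors, carrier flags) is kept in a sidecar so that
#' analysis code cannot consume it accidentally.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort`: list with `subjects` (data.frame of
#'   subject_id, age, covariates, one 0/1 column per condition), `features`
#'   (numeric matrix, columns `f0001`...), `hidden_truth` (data.frame with
#'   latent factors and carrier flags), `feature_roles` (character vector
#'   "age"/"disease"/"noise" per column), and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  cfg <- config
  n <- cfg$n_subjects
  withr::with_seed(cfg$seed, {
    age <- runif(n, cfg$age_min, cfg$age_max)
    covs <- data.frame(
      sex = rbinom(n, 1, 0.5),
      ses = rnorm(n),
      deprivation = rnorm(n),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n)
    )
    C <- as.matrix(covs)
    eta_base <- drop(C %*% cfg$covariates$diagnosis_log_odds[colnames(C)])

    cond_names <- vapply(cfg$conditions, `[[`, "", "name")
    labels <- matrix(0L, n, length(cond_names),
                     dimnames = list(NULL, cond_names))
    for (i in seq_along(cfg$conditions)) {
      cc <- cfg$conditions[[i]]
      eta <- cc$confounding_strength * eta_base
      b0 <- calibrate_intercept(eta, cc$prevalence)
      labels[, i] <- rbinom(n, 1, plogis(b0 + eta))
    }
    diagnosed <- rowSums(labels) > 0

    # undiagnosed carriers: disease effect without the label
    carriers <- matrix(0L, n, length(cond_names),
                       dimnames = list(NULL, cond_names))
    if (cfg$contamination_rate > 0) {
      undiag <- which(!diagnosed)
      is_carrier <- rbinom(length(undiag), 1, cfg$contamination_rate) == 1L
      which_cond <- sample.int(length(cond_names), sum(is_carrier),
                               replace = TRUE,
                               prob = vapply(cfg$conditions, `[[`, 0, "prevalence"))
      carriers[cbind(undiag[is_carrier], which_cond)] <- 1L
    }
    effect <- labels | carriers  # who expresses each condition's feature effect

    age_c <- age - mean(c(cfg$age_min, cfg$age_max))
    g <- cfg$global_age_slope * age_c +
      drop(C %*% cfg$covariates$global_factor_effects[colnames(C)]) +
      rnorm(n, 0, cfg$global_factor_sd)
    for (i in seq_along(cfg$conditions)) {
      g <- g + effect[, i] * cfg$conditions[[i]]$global_shift * cfg$global_factor_sd
    }
    h <- if (cfg$head_size_sd > 0) {
      cfg$head_size_age_slope * age_c + rnorm(n, 0, cfg$head_size_sd)
    } else {
      rep(0, n)
    }

    p_age <- cfg$n_age_features
    p_dis <- cfg$n_disease_features
    p_noise <- cfg$n_noise_features
    X_age <- outer(age, cfg$age_loadings) +
      cfg$age_feature_g_loading * matrix(g, n, p_age) +
      outer(h, cfg$head_size_loadings) +
      matrix(rnorm(n * p_age, 0, cfg$age_feature_noise_sd), n, p_age)
    X_dis <- cfg$disease_age_slope * matrix(age, n, p_dis) +
      cfg$disease_feature_g_loading * matrix(g, n, p_dis) +
      matrix(rnorm(n * p_dis, 0, cfg$disease_feature_noise_sd), n, p_dis)
    for (i in seq_along(cfg$conditions)) {
      fs <- cfg$conditions[[i]]$focal_shifts
      if (!is.null(fs) && any(fs != 0)) {
        fs_full <- c(fs, rep(0, p_dis - length(fs)))
        X_dis <- X_dis + effect[, i] %o% fs_full
      }
    }
    X_noise <- if (p_noise > 0) {
      matrix(rnorm(n * p_noise, 0, cfg$noise_feature_sd), n, p_noise)
    } else {
      matrix(0, n, 0)
    }
    X <- cbind(X_age, X_dis, X_noise)
    colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))

    subjects <- data.frame(
      subject_id = sprintf("s%06d", seq_len(n)),
      age = age,
      covs,
      as.data.frame(labels),
      check.names = FALSE
    )
    hidden <- data.frame(
      subject_id = subjects$subject_id,
      global_factor = g,
      head_size_factor = h,
      setNames(as.data.frame(carriers), paste0("carrier_", cond_names)),
      any_carrier = as.integer(rowSums(carriers) > 0),
      check.names = FALSE
    )
    structure(
      list(subjects = subjects, features = X, hidden_truth = hidden,
           feature_roles = rep(c("age", "disease", "noise"),
                               c(p_age, p_dis, p_noise)),
           config = cfg),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cond <- condition_columns(x)
  cat("synthetic_cohort:", nrow(x$subjects), "subjects,",
      ncol(x$features), "features\n")
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", cond, colSums(x$subjects[cond])),
            collapse = ", "), "\n")
  invisible(x)
}

condition_columns <- function(cohort) {
  vapply(cohort$config$conditions, `[[`, "", "name")
}

# Subjects with no diagnosed condition (carriers count as undiagnosed).
is_undiagnosed <- function(cohort) {
  rowSums(as.matrix(cohort$subjects[condition_columns(cohort)])) == 0
}

subset_cohort <- function(cohort, idx) {
  out <- cohort
  out$subjects <- cohort$subjects[idx, , drop = FALSE]
  out$features <- cohort$features[idx, , drop = FALSE]
  out$hidden_truth <- cohort$hidden_truth[idx, , drop = FALSE]
  rownames(out$subjects) <- NULL
  rownames(out$hidden_truth) <- NULL
  out
}

#' Split a cohort into training and test pools
#'
#' Diagnosed subjects never enter training: the training pool holds only
#' undiagnosed subjects (which retains undiagnosed carriers at the configured
#' contamination rate), and the test pool holds every diagnosed subject plus a
#' held-out fraction of the undiagnosed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param test_fraction Fraction of undiagnosed subjects held out for testing,
#'   in (0, 1).
#' @param seed Integer seed for the held-out draw.
#' @return List with `train` and `test`, each a `synthetic_cohort` subset, and
#'   `train_idx`/`test_idx` giving row indices into the input cohort.
#' @export
split_cohort <- function(cohort, test_fraction = 0.3, seed = 1) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie in (0, 1)")
  }
  undiag <- which(is_undiagnosed(cohort))
  diag_idx <- setdiff(seq_len(nrow(cohort$subjects)), undiag)
  n_test_h <- round(test_fraction * length(undiag))
  test_h <- withr::with_seed(as.integer(seed), sample(undiag, n_test_h))
  train_idx <- sort(setdiff(undiag, test_h))
  test_idx <- sort(c(test_h, diag_idx))
  list(train = subset_cohort(cohort, train_idx),
       test = subset_cohort(cohort, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Write / read a cohort as plain-text CSV
#'
#' The subject table and features go to one wide CSV (subject_id, age,
#' covariates, one 0/1 column per condition, feature columns `f0001`...); the
#' hidden truth goes to an optional sidecar CSV; the generator configuration to
#' YAML. [read_cohort_csv()] accepts the same dialect for user-supplied data,
#' in which case the truth sidecar is absent and condition/feature columns are
#' inferred from names.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Path of the main CSV.
#' @param truth_path Optional path for the hidden-truth sidecar CSV.
#' @param config_path Optional path for the generator config YAML.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL,
                             config_path = NULL) {
  wide <- cbind(cohort$subjects, as.data.frame(cohort$features))
  write.csv(wide, path, row.names = FALSE)
  if (!is.null(truth_path)) {
    write.csv(cohort$hidden_truth, truth_path, row.names = FALSE)
  }
  if (!is.null(config_path)) {
    cfg <- cohort$config
    cfg$conditions <- lapply(cfg$conditions, unclass)
    yaml::write_yaml(unclass(cfg), config_path)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param condition_cols,feature_cols Column names for conditions and features;
#'   by default conditions are the non-covariate, non-id 0/1 columns preceding
#'   the feature block and features are the columns matching `^f[0-9]+$`.
#' @export
read_cohort_csv <- function(path, truth_path = NULL, condition_cols = NULL,
                            feature_cols = NULL) {
  wide <- read.csv(path, check.names = FALSE)
  if (nrow(wide) == 0L) stop("cohort CSV is empty: ", path)
  for (col in c("subject_id", "age")) {
    if (!col %in% names(wide)) stop("required column missing: ", col)
  }
  if (is.null(feature_cols)) {
    feature_cols <- grep("^f[0-9]+$", names(wide), value = TRUE)
  }
  if (length(feature_cols) == 0L) stop("required column missing: features (f0001...)")
  if (is.null(condition_cols)) {
    known <- c("subject_id", "age", covariate_names(), feature_cols)
    condition_cols <- setdiff(names(wide), known)
  }
  if (length(condition_cols) == 0L) stop("required column missing: condition labels")
  subjects <- wide[, setdiff(names(wide), feature_cols), drop = FALSE]
  features <- as.matrix(wide[, feature_cols, drop = FALSE])
  hidden <- if (!is.null(truth_path) && file.exists(truth_path)) {
    read.csv(truth_path, check.names = FALSE)
  } else {
    data.frame(subject_id = subjects$subject_id)
  }
  conditions <- lapply(condition_cols, function(nm) {
    prev <- mean(subjects[[nm]])
    condition_spec(nm, prevalence = min(max(prev, 1e-6), 0.499))
  })
  structure(
    list(subjects = subjects, features = features, hidden_truth = hidden,
         feature_roles = rep(NA_character_, ncol(features)),
         config = list(conditions = conditions)),
    class = "synthetic_cohort"
  )
}
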
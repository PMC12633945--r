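test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_subjects = 500, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$features, b$features)
  expect_identical(a$hidden_truth, b$hidden_truth)
  c2 <- generate_cohort(generator_config(n_subjects = 500, seed = 100))
  expect_false(identical(a$features, c2$features))
})

test_that("invalid configurations are rejected with named violations", {
  expect_error(generator_config(contamination_rate = 1), "contamination_rate")
  expect_error(generator_config(age_min = 80, age_max = 45), "age_min")
  expect_error(generator_config(age_feature_noise_sd = 5,
                                disease_feature_noise_sd = 4),
               "age_feature_noise_sd")
  expect_error(generator_config(global_factor_sd = -1), "global_factor_sd")
  expect_error(condition_spec("x", prevalence = 0.6), "prevalence")
  expect_error(generator_config(conditions = list(
    condition_spec("a", 0.1), condition_spec("a", 0.1))), "unique")
})

test_that("null-effect configuration leaves no case/control feature difference", {
  co <- generate_cohort(generator_config(
    n_subjects = 20000, conditions = null_conditions(confounding = 0),
    contamination_rate = 0, seed = 3))
  cond <- c("global_strong", "global_weak", "focal")
  for (cn in cond) {
    lab <- co$subjects[[cn]]
    smd <- apply(co$features, 2, function(x) {
      (mean(x[lab == 1]) - mean(x[lab == 0])) / sd(x)
    })
    se <- sqrt(1 / sum(lab == 1) + 1 / sum(lab == 0))
    expect_lt(max(abs(smd)), 4.5 * se)   # max over 60 null draws
    expect_lt(abs(mean(smd)), se)
  }
})

test_that("global factor noise SD matches its configured value (Monte Carlo)", {
  co <- generate_cohort(generator_config(
    n_subjects = 20000, global_factor_sd = 2, global_age_slope = 0,
    conditions = null_conditions(), contamination_rate = 0,
    covariates = within_zero_g_effects(), seed = 5))
  expect_lt(abs(sd(co$hidden_truth$global_factor) - 2) / 2, 0.02)
})

test_that("empirical prevalence tracks the configured targets", {
  co <- small_cohort(n = 20000, seed = 7)
  prev <- colMeans(co$subjects[c("global_strong", "global_weak", "focal")])
  target <- c(0.02, 0.05, 0.03)
  tol <- 3 * sqrt(target * (1 - target) / 20000)
  expect_true(all(abs(prev - target) < tol))
})

test_that("split keeps diagnosed subjects out of training and pools disjoint", {
  co <- small_cohort(n = 5000, seed = 11)
  sp <- split_cohort(co, test_fraction = 0.3, seed = 2)
  cond <- c("global_strong", "global_weak", "focal")
  expect_true(all(rowSums(sp$train$subjects[cond]) == 0))
  expect_length(intersect(sp$train$subjects$subject_id,
                          sp$test$subjects$subject_id), 0)
  expect_setequal(c(sp$train$subjects$subject_id, sp$test$subjects$subject_id),
                  co$subjects$subject_id)
  # all diagnosed subjects are in the test pool
  n_diag <- sum(rowSums(co$subjects[cond]) > 0)
  expect_equal(sum(rowSums(sp$test$subjects[cond]) > 0), n_diag)
  expect_error(split_cohort(co, test_fraction = 1.2), "test_fraction")
})

test_that("near-zero prevalence gives an (1 - test_fraction) healthy train pool", {
  cfg <- generator_config(
    n_subjects = 3000,
    conditions = list(condition_spec("rare", prevalence = 1e-6)),
    contamination_rate = 0, seed = 13)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$subjects$rare), 0)
  sp <- split_cohort(co, test_fraction = 0.25, seed = 1)
  expect_equal(nrow(sp$train$subjects), round(0.75 * 3000))
  expect_equal(sum(sp$test$subjects$rare), 0)
})

test_that("contamination rate is realized in the training pool", {
  co <- generate_cohort(generator_config(n_subjects = 20000,
                                         contamination_rate = 0.1, seed = 17))
  sp <- split_cohort(co, test_fraction = 0.3, seed = 4)
  frac <- mean(sp$train$hidden_truth$any_carrier)
  n <- nrow(sp$train$subjects)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("disease features have higher residual variance than age features", {
  co <- small_cohort(n = 10000, seed = 19)
  resid_var <- sapply(seq_len(ncol(co$features)), function(j) {
    var(lm.fit(cbind(1, co$subjects$age), co$features[, j])$residuals)
  })
  expect_gt(min(resid_var[co$feature_roles == "disease"]),
            max(resid_var[co$feature_roles == "age"]))
})

test_that("regressing age features on age recovers the configured loadings", {
  cfg <- generator_config(n_subjects = 8000, seed = 23)
  co <- generate_cohort(cfg)
  X <- cbind(1, co$subjects$age)
  for (j in c(1, 25, 50)) {
    fit <- lm(co$features[, j] ~ co$subjects$age)
    est <- coef(summary(fit))[2, ]
    # marginal slope = direct loading plus the age trends inherited from the
    # global and head-size factors
    implied <- cfg$age_loadings[j] +
      cfg$age_feature_g_loading * cfg$global_age_slope +
      cfg$head_size_loadings[j] * cfg$head_size_age_slope
    expect_lt(abs(est["Estimate"] - implied), 3 * est["Std. Error"])
  }
})

test_that("cohort CSV round-trips and the truth sidecar stays separate", {
  co <- small_cohort(n = 300, seed = 29)
  path <- withr::local_tempfile(fileext = ".csv")
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path, truth_path = tpath)
  back <- read_cohort_csv(path, truth_path = tpath)
  expect_equal(back$subjects$age, co$subjects$age, tolerance = 1e-12)
  expect_equal(unname(back$features), unname(co$features), tolerance = 1e-12)
  expect_equal(back$hidden_truth$global_factor, co$hidden_truth$global_factor,
               tolerance = 1e-12)
  # reading without the sidecar must not expose ground truth
  plain <- read_cohort_csv(path)
  expect_false("global_factor" %in% names(plain$hidden_truth))
})
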
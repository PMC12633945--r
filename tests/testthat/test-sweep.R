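test_that("a one-point grid collapses the sweep and region report", {
  co <- small_cohort(n = 3000, seed = 61)
  sw <- run_alpha_sweep(co, grid = 10, n_train = 1000, n_resamples = 2,
                        seed = 1, attributions = FALSE)
  expect_equal(nrow(sw$aggregate_mae), 1)
  reg <- identify_regions(sw)
  expect_equal(reg$alpha_mae_opt, 10)
  expect_true(all(reg$conditions$alpha_d_opt == 10))
  expect_equal(reg$alpha_majority_opt, 10)
})

test_that("the sweep is reproducible bit-for-bit under the master seed", {
  co <- small_cohort(n = 3000, seed = 62)
  a <- run_alpha_sweep(co, grid = alpha_grid(5), n_train = 800,
                       n_resamples = 2, seed = 9, attributions = TRUE)
  b <- run_alpha_sweep(co, grid = alpha_grid(5), n_train = 800,
                       n_resamples = 2, seed = 9, attributions = TRUE)
  expect_identical(a$mae, b$mae)
  expect_identical(a$d, b$d)
  expect_identical(a$attribution, b$attribution)
  c2 <- run_alpha_sweep(co, grid = alpha_grid(5), n_train = 800,
                        n_resamples = 2, seed = 10, attributions = FALSE)
  expect_false(identical(a$mae, c2$mae))
})

test_that("sweep cells match a from-scratch refit through the model surface", {
  co <- small_cohort(n = 3000, seed = 63)
  grid <- alpha_grid(9, 1e-3, 1e4)
  sw <- run_alpha_sweep(co, grid = grid, n_train = 1000, n_resamples = 2,
                        seed = 4, attributions = FALSE)
  seeds <- brainagegap:::derive_seeds(4, 4)
  sp <- sw$split
  cond <- c("global_strong", "global_weak", "focal")
  healthy_test <- rowSums(as.matrix(sp$test$subjects[cond])) == 0
  for (spot in list(c(1, 1), c(5, 2), c(9, 1))) {
    k <- spot[1]; r <- spot[2]
    tr_idx <- withr::with_seed(seeds[2 + r],
                               sample.int(nrow(sp$train$subjects), 1000))
    m <- fit_ridge(sp$train$features[tr_idx, ],
                   sp$train$subjects$age[tr_idx], grid[k])
    preds <- predict_age(m, sp$test$features)
    gaps <- make_gap_table(sp$test$subjects$subject_id,
                           sp$test$subjects$age, preds)
    gaps <- apply_bias_correction(gaps, fit_bias_correction(gaps))
    expect_equal(sw$mae[k, r],
                 mean_absolute_error(sp$test$subjects$age[healthy_test],
                                     preds[healthy_test]),
                 tolerance = 1e-8)
    d_direct <- matched_effect_size(gaps, sw$matched$global_weak, n_boot = 0)$d
    expect_equal(unname(sw$d[k, "global_weak", r]), d_direct, tolerance = 1e-8)
  }
})

test_that("pool shortfall is reported by name", {
  co <- small_cohort(n = 1000, seed = 64)
  expect_error(run_alpha_sweep(co, grid = 10, n_train = 5000, seed = 1),
               "training pool")
})

test_that("null condition effects flatten the d curves at every alpha", {
  co <- generate_cohort(generator_config(
    n_subjects = 10000, conditions = null_conditions(),
    contamination_rate = 0, seed = 65))
  sw <- run_alpha_sweep(co, grid = alpha_grid(8), n_train = 3000,
                        n_resamples = 3, seed = 2, attributions = FALSE)
  expect_lt(max(abs(sw$aggregate_d$d_mean)), 0.15)
  reg <- identify_regions(sw)
  expect_lt(max(abs(reg$conditions$sensitivity_gain)), 0.2)
})

test_that("region finding on constructed curves", {
  grid <- alpha_grid(11, 1e-2, 1e2)
  fake <- function(mae, d_list, d_se = 0.01) {
    agg_d <- do.call(rbind, lapply(names(d_list), function(cn) {
      data.frame(alpha = grid, condition = cn, d_mean = d_list[[cn]],
                 d_se = d_se)
    }))
    structure(list(grid = grid,
                   aggregate_mae = data.frame(alpha = grid, mae_mean = mae,
                                              mae_se = 0.01),
                   aggregate_d = agg_d,
                   conditions = names(d_list)),
              class = "sweep_result")
  }
  # monotone-decreasing d with U-shaped MAE: detection optimum at the grid
  # minimum, no inverse relationship
  u_mae <- 3 + (log10(grid) - 0)^2
  dec_d <- seq(0.5, 0.1, length.out = 11)
  reg <- identify_regions(fake(u_mae, list(a = dec_d)))
  expect_equal(reg$conditions$alpha_d_opt, grid[1])
  expect_false(reg$conditions$inverse_relationship)
  # two conditions with identical curves: majority optimum at the common argmax
  peak_d <- c(seq(0.1, 0.5, length.out = 6), seq(0.45, 0.25, length.out = 5))
  reg2 <- identify_regions(fake(u_mae, list(a = peak_d, b = peak_d),
                                d_se = 1e-6))
  expect_equal(reg2$alpha_majority_opt, grid[6])
  expect_equal(reg2$majority_count, 2)
  # rising d to the right of the MAE optimum: inverse relationship flagged
  rise_d <- seq(0.1, 0.5, length.out = 11)
  reg3 <- identify_regions(fake(u_mae, list(a = rise_d)))
  expect_true(reg3$conditions$inverse_relationship)
  expect_gt(reg3$conditions$alpha_d_opt, reg3$alpha_mae_opt)
})

test_that("ties break toward larger alpha for MAE and smaller for d", {
  grid <- c(1, 10, 100)
  flat <- structure(
    list(grid = grid,
         aggregate_mae = data.frame(alpha = grid, mae_mean = c(3, 3, 4),
                                    mae_se = 0),
         aggregate_d = data.frame(alpha = grid, condition = "a",
                                  d_mean = c(0.2, 0.5, 0.5), d_se = 0),
         conditions = "a"),
    class = "sweep_result")
  reg <- identify_regions(flat)
  expect_equal(reg$alpha_mae_opt, 10)       # tie 1 vs 10 -> larger
  expect_equal(reg$conditions$alpha_d_opt, 10)  # tie 10 vs 100 -> smaller
})

test_that("train-size sweep: more healthy training data does not hurt accuracy", {
  co <- small_cohort(n = 8000, seed = 66)
  tbl <- run_trainsize_sweep(co, sizes = c(300, 1200, 4000),
                             alpha_policy = "cv", grid = alpha_grid(12),
                             n_resamples = 3, seed = 3)
  one <- tbl[tbl$condition == "global_weak", ]
  expect_equal(nrow(one), 3)
  # nonincreasing within combined standard errors
  for (i in 1:2) {
    expect_lt(one$mae_mean[i + 1],
              one$mae_mean[i] + 2 * (one$mae_se[i] + one$mae_se[i + 1]) + 0.05)
  }
  expect_lt(one$mae_mean[3], one$mae_mean[1])
  single <- run_trainsize_sweep(co, sizes = 500, alpha_policy = "fixed",
                                alpha = 50, n_resamples = 2, seed = 4)
  expect_equal(unique(single$size), 500)
  expect_error(run_trainsize_sweep(co, sizes = 1e6, seed = 1), "exceeds")
})
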
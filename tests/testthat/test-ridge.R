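test_that("alpha grid defaults to 100 log-spaced points from 1e-5 to 1e5", {
  g <- alpha_grid()
  expect_length(g, 100)
  expect_equal(g[1], 1e-5)
  expect_equal(g[100], 1e5)
  expect_true(all(diff(g) > 0))
  expect_equal(sd(diff(log(g))), 0, tolerance = 1e-12)
})

test_that("OLS limit interpolates and infinite shrinkage predicts the mean", {
  X <- matrix(c(-1, 0, 1), ncol = 1, dimnames = list(NULL, "f0001"))
  y <- c(1, 2, 3)
  m0 <- fit_ridge(X, y, alpha = 0)
  expect_equal(predict_age(m0, X), y, tolerance = 1e-10)
  minf <- fit_ridge(X, y, alpha = 1e12)
  expect_equal(predict_age(minf, X), rep(2, 3), tolerance = 1e-6)
})

test_that("weights match the dense normal-equation oracle", {
  prob <- random_problem(50, 20, seed = 8)
  m <- fit_ridge(prob$X, prob$y, alpha = 3.7)
  expect_lt(max(abs(m$weights - drop(ridge_oracle(prob$X, prob$y, 3.7)))), 1e-8)
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- cbind(f0001 = rnorm(10), f0002 = rep(1, 10))
  expect_error(fit_ridge(X, rnorm(10), 1), "f0002")
  prob <- random_problem(10, 20, seed = 2)
  expect_error(fit_ridge(prob$X, prob$y, 0), "alpha > 0")
  m <- fit_ridge(prob$X[, 1:3], prob$y, 1)
  expect_error(predict_age(m, prob$X[, 1:5]), "mismatch")
})

test_that("prediction is the affine map through the scaler", {
  model <- structure(
    list(alpha = 1, weights = c(f0001 = 2), intercept = 60,
         scaler = list(mean = c(f0001 = 1), sd = c(f0001 = 1)),
         train_target_mean = 60, feature_names = "f0001"),
    class = "ridge_model")
  expect_equal(predict_age(model, matrix(3, dimnames = list(NULL, "f0001"))), 64)
  model$weights[] <- 0
  expect_equal(predict_age(model, matrix(-5, dimnames = list(NULL, "f0001"))), 60)
})

test_that("OLS residuals are orthogonal to the features (n > p, alpha = 0)", {
  prob <- random_problem(100, 5, seed = 3)
  m <- fit_ridge(prob$X, prob$y, 0)
  resid <- prob$y - predict_age(m, prob$X)
  expect_lt(max(abs(crossprod(scale(prob$X), resid))), 1e-8)
})

test_that("weight norm shrinks monotonically in alpha", {
  prob <- random_problem(80, 15, seed = 4)
  norms <- vapply(alpha_grid(25), function(a) {
    sqrt(sum(fit_ridge(prob$X, prob$y, a)$weights^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("rescaling a raw feature column leaves predictions unchanged", {
  prob <- random_problem(60, 6, seed = 5)
  m1 <- fit_ridge(prob$X, prob$y, 2)
  X2 <- prob$X
  X2[, 3] <- X2[, 3] * 1000
  m2 <- fit_ridge(X2, prob$y, 2)
  expect_equal(predict_age(m2, X2), predict_age(m1, prob$X), tolerance = 1e-9)
})

test_that("refitting on identical input reproduces the identical model", {
  prob <- random_problem(40, 10, seed = 6)
  expect_identical(fit_ridge(prob$X, prob$y, 1.5),
                   fit_ridge(prob$X, prob$y, 1.5))
})

test_that("mean absolute error: hand values and the uniform-age limit", {
  expect_equal(mean_absolute_error(c(60, 70), c(60, 70)), 0)
  expect_equal(mean_absolute_error(c(60, 70), c(62, 66)), 3)
  expect_error(mean_absolute_error(1:3, 1:2), "length mismatch")
  expect_error(mean_absolute_error(numeric(0), numeric(0)), "empty")
  # constant predictor at the mean of uniform(45, 80): MAE -> range/4
  age <- withr::with_seed(9, runif(2e5, 45, 80))
  expect_equal(mean_absolute_error(age, rep(mean(age), length(age))), 35 / 4,
               tolerance = 0.01)
})

test_that("LOO fast path matches naive leave-one-out refits on a fixed design", {
  prob <- random_problem(40, 6, seed = 10)
  grid <- alpha_grid(7, 1e-2, 1e3)
  fast <- select_alpha_cv(prob$X, prob$y, grid, method = "loo")
  # naive oracle: standardize once (fixed design), then refit per left-out
  # row, jointly estimating the unpenalized intercept with the weights
  mu <- colMeans(prob$X); sdv <- apply(prob$X, 2, sd)
  Xs <- sweep(sweep(prob$X, 2, mu), 2, sdv, "/")
  Z <- cbind(1, Xs)
  naive <- vapply(grid, function(a) {
    P <- diag(c(0, rep(a, ncol(Xs))))
    errs <- vapply(seq_len(nrow(Xs)), function(i) {
      Zi <- Z[-i, , drop = FALSE]; yi <- prob$y[-i]
      theta <- qr.solve(crossprod(Zi) + P, crossprod(Zi, yi))
      (prob$y[i] - drop(Z[i, ] %*% theta))^2
    }, 0)
    mean(errs)
  }, 0)
  expect_equal(fast$cv_error, naive, tolerance = 1e-6)
})

test_that("k-fold CV curve matches the brute-force refit oracle everywhere", {
  prob <- random_problem(200, 50, noise_sd = 5, seed = 11)
  grid <- alpha_grid(12, 1e-3, 1e4)
  res <- select_alpha_cv(prob$X, prob$y, grid, n_folds = 5, seed = 77,
                         method = "kfold")
  folds <- withr::with_seed(77L, sample(rep_len(1:5, 200)))
  naive <- sapply(grid, function(a) {
    se <- numeric(200)
    for (k in 1:5) {
      m <- fit_ridge(prob$X[folds != k, ], prob$y[folds != k], a)
      se[folds == k] <- (prob$y[folds == k] -
                           predict_age(m, prob$X[folds == k, ]))^2
    }
    mean(se)
  })
  expect_equal(res$cv_error, naive, tolerance = 1e-8)
  expect_equal(res$best_alpha, grid[which.min(naive)])
})

test_that("alpha selection handles noiseless and degenerate grids", {
  withr::with_seed(12, {
    X <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "f0001"))
    y <- 50 + 2 * X[, 1]
  })
  res <- select_alpha_cv(X, y, alpha_grid(10, 1e-4, 1e2))
  expect_equal(res$best_alpha, 1e-4)
  expect_lt(res$cv_error[1], 1e-6)
  one <- select_alpha_cv(X, y, grid = 3.14)
  expect_equal(one$best_alpha, 3.14)
  expect_error(select_alpha_cv(X, y, grid = numeric(0)), "empty")
})

test_that("model JSON serialization round-trips losslessly", {
  prob <- random_problem(30, 4, seed = 13)
  m <- fit_ridge(prob$X, prob$y, 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-15)
  expect_equal(back$scaler$mean, m$scaler$mean, tolerance = 1e-15)
  expect_equal(back$scaler$sd, m$scaler$sd, tolerance = 1e-15)
  expect_equal(predict_age(back, prob$X), predict_age(m, prob$X),
               tolerance = 1e-12)
})
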
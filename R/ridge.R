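#' Log-spaced regularization grid
#'
#' @param n Number of grid points.
#' @param min,max Grid endpoints (inclusive).
#' @return Strictly increasing numeric vector of length `n`; default 100
#'   log-spaced points from 1e-5 to 1e5.
#' @export
alpha_grid <- function(n = 100, min = 1e-5, max = 1e5) {
  stopifnot(n >= 1, min > 0, max > min || n == 1)
  exp(seq(log(min), log(max), length.out = n))
}

# Standard scaler fit on training data only; zero-variance columns are an
# error because downstream weights live on the scaled space.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  bad <- which(!(sdv > 0))
  if (length(bad)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "))
  }
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a standard-scaled ridge regression brain-age model
#'
#' Features are standardized (scaler fit on the supplied training data only),
#' the age target is centered, and the weights solve the penalized normal
#' equations `(X'X + alpha I) w = X'(y - ybar)` on the scaled, centered data.
#' The penalty is on the coefficient vector directly (the sklearn convention,
#' no scaling by n); the intercept is the training mean age and is never
#' penalized.
#'
#' @param features Numeric matrix, one row per subject.
#' @param age Numeric vector of chronological ages (years).
#' @param alpha Non-negative L2 penalty.
#' @return A `ridge_model`: alpha, weights (scaled space), intercept (years),
#'   scaler, train_target_mean, feature_names.
#' @export
fit_ridge <- function(features, age, alpha) {
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(age), alpha >= 0)
  if (nrow(X) < 2) stop("need at least 2 training rows")
  if (anyNA(X) || anyNA(age)) stop("missing values in features or age")
  if (alpha == 0 && ncol(X) >= nrow(X)) {
    stop("singular system: alpha = 0 with p >= n; use alpha > 0")
  }
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  ybar <- mean(age)
  A <- crossprod(Xs) + diag(alpha, ncol(Xs))
  w <- tryCatch(
    drop(solve(A, crossprod(Xs, age - ybar))),
    error = function(e) stop("singular ridge system at alpha = ", alpha,
                             "; use alpha > 0 (", conditionMessage(e), ")")
  )
  structure(
    list(alpha = alpha, weights = setNames(w, colnames(X)),
         intercept = ybar, scaler = scaler, train_target_mean = ybar,
         feature_names = colnames(X)),
    class = "ridge_model"
  )
}

#' @export
print.ridge_model <- function(x, ...) {
  cat("ridge_model: alpha =", format(x$alpha), ",",
      length(x$weights), "features, intercept =",
      round(x$intercept, 2), "years\n")
  invisible(x)
}

#' Predict age from a fitted ridge model
#'
#' @param model A `ridge_model`.
#' @param features Numeric matrix with the model's feature columns.
#' @return Numeric vector of predicted ages (years).
#' @export
predict_age <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != length(model$weights)) {
    stop("feature count mismatch: model has ", length(model$weights),
         ", input has ", ncol(X))
  }
  if (!is.null(colnames(X)) && !is.null(model$feature_names) &&
      !identical(colnames(X), model$feature_names)) {
    stop("feature columns do not match the model's feature_names")
  }
  drop(model$intercept + apply_scaler(model$scaler, X) %*% model$weights)
}

# Full ridge path on pre-standardized, centered data via one SVD.
# Returns the p x n_alpha weight matrix; shared by CV and the sweeps.
ridge_path_weights <- function(Xs, y_centered, alphas) {
  sv <- svd(Xs)
  uty <- drop(crossprod(sv$u, y_centered))
  shrink <- sv$d / outer(sv$d^2, alphas, "+")   # length(d) x n_alpha
  sv$v %*% (shrink * uty)
}

#' Select the regularization strength by cross-validation
#'
#' The default method is the exact leave-one-out shortcut for ridge: residuals
#' are inflated by `1/(1 - h_ii)` where `h_ii` is the hat diagonal of the
#' penalized smoother (including the unpenalized intercept), computed for the
#' whole grid from one SVD of the standardized design. The `"kfold"` method
#' refits scaler and model per fold. Ties in mean squared CV error break
#' toward larger alpha (more shrinkage).
#'
#' @param features Numeric matrix.
#' @param age Numeric vector (years).
#' @param grid Increasing positive grid of alphas, e.g. [alpha_grid()].
#' @param n_folds Folds for `method = "kfold"`.
#' @param seed Seed for the fold assignment.
#' @param method `"loo"` (default) or `"kfold"`.
#' @return List with `best_alpha`, `cv_error` (mean squared error per grid
#'   point), `grid`, and `method`.
#' @export
select_alpha_cv <- function(features, age, grid = alpha_grid(),
                            n_folds = 5, seed = 1,
                            method = c("loo", "kfold")) {
  method <- match.arg(method)
  X <- as.matrix(features)
  n <- nrow(X)
  if (length(grid) == 0L) stop("empty alpha grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  stopifnot(n >= 2, length(age) == n)
  cv <- if (method == "loo") {
    loo_cv_errors(X, age, grid)
  } else {
    if (n_folds < 2 || n < n_folds) stop("need 2 <= n_folds <= n rows")
    kfold_cv_errors(X, age, grid, n_folds, seed)
  }
  best <- max(grid[cv == min(cv)])
  list(best_alpha = best, cv_error = cv, grid = grid, method = method)
}

# Exact LOO on the once-standardized design: hat diagonal
# h_ii = 1/n + sum_k u_ik^2 d_k^2/(d_k^2 + alpha).
loo_cv_errors <- function(X, y, grid) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(Xs)
  uty <- drop(crossprod(sv$u, yc))
  n <- nrow(Xs)
  vapply(grid, function(a) {
    f <- sv$d^2 / (sv$d^2 + a)
    fitted <- drop(sv$u %*% (f * uty))
    h <- 1 / n + rowSums(sweep(sv$u^2, 2, f, "*"))
    mean(((yc - fitted) / (1 - h))^2)
  }, 0)
}

kfold_cv_errors <- function(X, y, grid, n_folds, seed) {
  n <- nrow(X)
  folds <- withr::with_seed(as.integer(seed),
                            sample(rep_len(seq_len(n_folds), n)))
  se <- matrix(NA_real_, n, length(grid))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    scaler <- fit_scaler(X[tr, , drop = FALSE])
    Xs_tr <- apply_scaler(scaler, X[tr, , drop = FALSE])
    ybar <- mean(y[tr])
    W <- ridge_path_weights(Xs_tr, y[tr] - ybar, grid)
    pred <- ybar + apply_scaler(scaler, X[!tr, , drop = FALSE]) %*% W
    se[!tr, ] <- (y[!tr] - pred)^2
  }
  colMeans(se)
}

#' Mean absolute error in years
#'
#' @param y,yhat Equal-length numeric vectors.
#' @return Mean of `|y - yhat|`.
#' @export
mean_absolute_error <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) == 0L) stop("empty input")
  mean(abs(y - yhat))
}

#' Serialize / restore a ridge model as JSON
#'
#' Round-trips are lossless to full double precision.
#'
#' @param model A `ridge_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `ridge_model` (read).
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(alpha = model$alpha,
         weights = unname(model$weights),
         intercept = model$intercept,
         train_target_mean = model$train_target_mean,
         scaler_mean = unname(model$scaler$mean),
         scaler_sd = unname(model$scaler$sd),
         feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha = j$alpha,
         weights = setNames(j$weights, j$feature_names),
         intercept = j$intercept,
         scaler = list(mean = setNames(j$scaler_mean, j$feature_names),
                       sd = setNames(j$scaler_sd, j$feature_names)),
         train_target_mean = j$train_target_mean,
         feature_names = j$feature_names),
    class = "ridge_model"
  )
}
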
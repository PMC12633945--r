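# Shared fixtures, built in code.

# A small cohort for fast unit tests.
small_cohort <- function(n = 4000, seed = 42, ...) {
  generate_cohort(generator_config(n_subjects = n, seed = seed, ...))
}

# Conditions with all effects switched off (null scenario); diagnosis stays
# confounded with covariates unless confounding is also zeroed.
null_conditions <- function(confounding = 1) {
  list(
    condition_spec("global_strong", prevalence = 0.02, global_shift = 0,
                   confounding_strength = confounding),
    condition_spec("global_weak", prevalence = 0.05, global_shift = 0,
                   confounding_strength = confounding),
    condition_spec("focal", prevalence = 0.03,
                   confounding_strength = confounding)
  )
}

# Covariate spec whose covariates do not touch the global factor.
within_zero_g_effects <- function() {
  cs <- covariate_spec()
  cs$global_factor_effects[] <- 0
  cs
}

# A random regression problem for ridge oracles.
random_problem <- function(n, p, noise_sd = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("f%04d", seq_len(p))
    beta <- rnorm(p)
    y <- 60 + drop(X %*% beta) + rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
}

# Independent dense normal-equation oracle for ridge on standardized data.
ridge_oracle <- function(X, y, alpha) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  qr.solve(crossprod(Xs) + alpha * diag(ncol(Xs)),
           crossprod(Xs, y - mean(y)))
}

# All permutations of a vector (for small brute-force assignment oracles).
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- vector("list", 0)
  for (i in seq_along(v)) {
    for (p in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# The full-scale 10-seed study is shared by several acceptance checks;
# compute it once per test run.
acceptance_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_headline_study(n_seeds = 10, master_seed = 1)
    }
    cache
  }
})
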
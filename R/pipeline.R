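#' Full-experiment run configuration
#'
#' Bundles every tunable of the end-to-end experiment; validated up front and
#' persisted verbatim alongside the outputs.
#'
#' @param generator A [generator_config()].
#' @param grid Alpha grid.
#' @param n_train Training subjects per resample.
#' @param n_resamples Training resamples.
#' @param n_folds CV folds (kept for the CV alpha-selection stages).
#' @param n_boot Bootstrap resamples for effect-size SEs.
#' @param caliper_sd Matching caliper in logit-SD units.
#' @param test_fraction Held-out fraction of undiagnosed subjects.
#' @param master_seed Single seed from which all stage seeds derive.
#' @param output_dir Directory for all artifacts.
#' @return A validated `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       grid = alpha_grid(),
                       n_train = 5000, n_resamples = 10,
                       n_folds = 5, n_boot = 1000,
                       caliper_sd = 0.25, test_fraction = 0.3,
                       master_seed = 1, output_dir = tempfile("brainage_run_")) {
  stopifnot(inherits(generator, "generator_config"),
            length(grid) >= 1, all(grid > 0),
            n_train >= 2, n_resamples >= 1, n_folds >= 2, n_boot >= 100,
            caliper_sd > 0, test_fraction > 0, test_fraction < 1)
  structure(
    list(generator = generator, grid = grid, n_train = n_train,
         n_resamples = n_resamples, n_folds = n_folds, n_boot = n_boot,
         caliper_sd = caliper_sd, test_fraction = test_fraction,
         master_seed = as.integer(master_seed), output_dir = output_dir),
    class = "run_config"
  )
}

# Hashes the scientific configuration only; output_dir does not affect it.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  stripped <- rapply(cfg, unclass, how = "replace")
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full experiment: generate, split, match, sweep, attribute, report
#'
#' Executes every stage under seeds derived from the master seed, writes all
#' intermediate artifacts (cohort CSV + truth sidecar + config YAML, matched
#' pair CSVs, balance JSON, sweep per-run and aggregate CSVs, attribution CSV,
#' region JSON) into `output_dir`, and returns the run report. Stage errors
#' abort with the stage name; artifacts written so far remain on disk.
#'
#' @param config A [run_config()].
#' @return A `run_report`: config hash, per-stage record counts and wall-clock
#'   seconds, region report, per-condition effect sizes with bootstrap SEs at
#'   the accuracy- and detection-optimal alphas, and the software version.
#' @export
run_full_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$master_seed, 4)
  counts <- list(); clock <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    clock[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  od <- function(...) file.path(config$output_dir, ...)

  gen_cfg <- config$generator
  gen_cfg$seed <- seeds[1]
  cohort <- stage("generate", {
    co <- generate_cohort(gen_cfg)
    write_cohort_csv(co, od("cohort.csv"), od("cohort_truth.csv"),
                     od("generator_config.yaml"))
    co
  })
  counts$subjects <- nrow(cohort$subjects)

  split <- stage("split", split_cohort(cohort, config$test_fraction,
                                       seed = seeds[2]))
  counts$train_pool <- nrow(split$train$subjects)
  counts$test_pool <- nrow(split$test$subjects)

  matched <- stage("match", {
    m <- match_test_cohorts(split$test, caliper_sd = config$caliper_sd,
                            seed = seeds[3])
    for (cn in names(m)) {
      write.csv(m[[cn]]$pairs, od(paste0("matched_", cn, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(m, function(mc) list(
        n_pairs = mc$n_pairs, caliper_width = mc$caliper_width,
        n_unmatched = length(mc$unmatched_patients),
        balance = mc$balance)),
      od("balance.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    m
  })
  counts$matched_pairs <- vapply(matched, `[[`, 0L, "n_pairs")

  sweep <- stage("sweep", {
    sw <- run_alpha_sweep(cohort, grid = config$grid,
                          n_train = config$n_train,
                          n_resamples = config$n_resamples,
                          seed = seeds[4], split = split, matched = matched,
                          attributions = TRUE)
    per_run <- data.frame(
      alpha = rep(sw$grid, sw$n_resamples),
      resample = rep(seq_len(sw$n_resamples), each = length(sw$grid)),
      mae = as.vector(sw$mae))
    write.csv(per_run, od("sweep_mae.csv"), row.names = FALSE)
    write.csv(sw$aggregate_mae, od("sweep_mae_aggregate.csv"), row.names = FALSE)
    write.csv(sw$aggregate_d, od("sweep_d_aggregate.csv"), row.names = FALSE)
    sw
  })
  counts$sweep_cells <- length(sweep$grid) * sweep$n_resamples

  attribution <- stage("attribute", {
    write.csv(sweep$attribution, od("attribution.csv"), row.names = FALSE)
    sweep$attribution
  })

  report <- stage("report", {
    regions <- identify_regions(sweep)
    jsonlite::write_json(
      list(alpha_mae_opt = regions$alpha_mae_opt,
           alpha_majority_opt = regions$alpha_majority_opt,
           conditions = regions$conditions),
      od("regions.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
    regions
  })

  # bootstrap SEs for d at the two headline alphas, per condition
  effects <- effect_sizes_at_optima(sweep, report, n_boot = config$n_boot,
                                    seed = seeds[4])
  write.csv(effects, od("effect_sizes.csv"), row.names = FALSE)

  rep_obj <- structure(
    list(config_hash = config_hash(config),
         counts = counts,
         regions = report,
         effect_sizes = effects,
         version = as.character(utils::packageVersion("brainagegap")),
         wall_clock = clock,
         output_dir = config$output_dir),
    class = "run_report"
  )
  jsonlite::write_json(
    list(config_hash = rep_obj$config_hash, counts = counts,
         alpha_mae_opt = report$alpha_mae_opt,
         alpha_majority_opt = report$alpha_majority_opt,
         version = rep_obj$version, wall_clock = clock),
    od("run_report.json"), auto_unbox = TRUE, digits = NA)
  rep_obj
}

# Cohen's d with bootstrap SE at alpha_mae_opt and alpha_d_opt, recomputed
# from the first resample's corrected gaps for reporting.
effect_sizes_at_optima <- function(sweep, regions, n_boot = 1000, seed = 1) {
  grid <- sweep$grid
  df <- regions$conditions
  rows <- lapply(seq_len(nrow(df)), function(i) {
    cn <- df$condition[i]
    sub <- sweep$aggregate_d[sweep$aggregate_d$condition == cn, ]
    i_mae <- which(grid == df$alpha_mae_opt[i])[1]
    i_d <- which(grid == df$alpha_d_opt[i])[1]
    data.frame(condition = cn,
               alpha_mae_opt = df$alpha_mae_opt[i],
               alpha_d_opt = df$alpha_d_opt[i],
               d_at_mae_opt = sub$d_mean[i_mae],
               d_se_at_mae_opt = sub$d_se[i_mae],
               d_at_d_opt = sub$d_mean[i_d],
               d_se_at_d_opt = sub$d_se[i_d],
               mae_at_mae_opt = df$mae_at_mae_opt[i],
               mae_at_d_opt = df$mae_at_d_opt[i],
               n_pairs = sweep$matched[[cn]]$n_pairs)
  })
  do.call(rbind, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (brainagegap", x$version, ")\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  subjects:", x$counts$subjects, "| train pool:", x$counts$train_pool,
      "| test pool:", x$counts$test_pool, "\n")
  cat("  matched pairs:",
      paste(names(x$counts$matched_pairs), x$counts$matched_pairs,
            sep = "=", collapse = ", "), "\n")
  print(x$regions)
  invisible(x)
}

#' Load a cohort CSV with per-stage missing-data accounting
#'
#' Reads a wide cohort table (the [write_cohort_csv()] dialect, truth sidecar
#' optional) and attaches a validation report: row count, per-column
#' missingness, and rows that would be dropped by feature-using stages. Rows
#' with missing values are not removed here; each analysis stage excludes rows
#' missing in the columns it actually uses (see [complete_rows_for()]), so a
#' subject missing one feature is excluded from model fitting but retained for
#' covariate-only stages.
#'
#' @param path Cohort CSV path.
#' @param truth_path Optional truth sidecar path.
#' @return A `synthetic_cohort` with a `validation` element.
#' @export
load_cohort_csv <- function(path, truth_path = NULL) {
  cohort <- read_cohort_csv(path, truth_path)
  wide <- cbind(cohort$subjects, as.data.frame(cohort$features))
  miss <- colSums(is.na(wide))
  cohort$validation <- list(
    n_rows = nrow(wide),
    missing_by_column = miss[miss > 0],
    n_complete_feature_rows = sum(complete.cases(cohort$features)),
    n_complete_covariate_rows =
      sum(complete.cases(cohort$subjects))
  )
  cohort
}

#' Row indices complete in the columns a stage uses
#'
#' Implements analysis-by-analysis exclusion: a stage passes the columns it
#' consumes and gets back the rows it may use, with the drop count reported
#' via a message.
#'
#' @param cohort A `synthetic_cohort`.
#' @param use_features Does the stage consume the feature matrix?
#' @param subject_cols Subject-table columns the stage consumes.
#' @return Integer row indices.
#' @export
complete_rows_for <- function(cohort, use_features = FALSE,
                              subject_cols = c("subject_id", "age")) {
  ok <- complete.cases(cohort$subjects[, subject_cols, drop = FALSE])
  if (use_features) ok <- ok & complete.cases(cohort$features)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " row(s) excluded for this stage (missing values in ",
            if (use_features) "features or " else "", "required columns)")
  }
  which(ok)
}
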
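# Train-size analogue: accuracy improves with more healthy training data
# while matched effect sizes need not.

source("analysis/00_common.R")

cohort <- generate_cohort(generator_config(seed = master_seed))
tbl <- run_trainsize_sweep(cohort, sizes = c(500, 1000, 2000, 5000),
                           alpha_policy = "cv", grid = alpha_grid(30),
                           n_resamples = 10, seed = master_seed)
write.csv(tbl, file.path(out_dir, "trainsize.csv"), row.names = FALSE)

for (sz in unique(tbl$size)) {
  row <- tbl[tbl$size == sz, ][1, ]
  say("n_train = %4d: MAE %.2f +- %.2f years (median CV alpha %.3g)",
      sz, row$mae_mean, row$mae_se, row$alpha_median)
}
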
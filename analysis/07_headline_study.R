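# The headline claims over 10 independent end-to-end runs: detection-optimal
# regularization exceeds accuracy-optimal (with larger d and larger MAE
# there), attribution mass shifts onto global features, and the effect size
# peaks strictly inside the grid.

source("analysis/00_common.R")

study <- run_headline_study(n_seeds = 10, master_seed = master_seed)
print(study)

write.csv(study$runs, file.path(out_dir, "headline_runs.csv"),
          row.names = FALSE)
write.csv(study$seeds, file.path(out_dir, "headline_flags.csv"),
          row.names = FALSE)
say("per-seed tables written under %s", out_dir)
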
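# Generate the default synthetic cohort: 20,000 subjects, ages 45-80,
# 50 age-informative + 8 disease-sensitive + 2 noise features, three
# conditions with confounded diagnosis, 5% undiagnosed carriers.

source("analysis/00_common.R")

cfg <- generator_config(seed = master_seed)
cohort <- generate_cohort(cfg)
print(cohort)

write_cohort_csv(cohort,
                 file.path(out_dir, "cohort.csv"),
                 truth_path = file.path(out_dir, "cohort_truth.csv"),
                 config_path = file.path(out_dir, "generator_config.yaml"))

prev <- colMeans(cohort$subjects[c("global_strong", "global_weak", "focal")])
say("empirical prevalences: %s",
    paste(sprintf("%s=%.3f", names(prev), prev), collapse = ", "))
say("undiagnosed carriers: %.1f%% of cohort",
    100 * mean(cohort$hidden_truth$any_carrier))
say("cohort written to %s", file.path(out_dir, "cohort.csv"))
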
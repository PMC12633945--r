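# Build the matched patient/control cohorts used by all group comparisons:
# logistic propensity on age + confounders, greedy 1:1 matching with a
# 0.25-SD logit caliper, balance diagnostics before/after.

source("analysis/00_common.R")

cohort <- load_cohort_csv(file.path(out_dir, "cohort.csv"))
sp <- split_cohort(cohort, test_fraction = 0.3, seed = master_seed)
matched <- match_test_cohorts(sp$test, caliper_sd = 0.25, seed = master_seed)

for (cn in names(matched)) {
  m <- matched[[cn]]
  print(m)
  write.csv(m$pairs, file.path(out_dir, paste0("matched_", cn, ".csv")),
            row.names = FALSE)
  bal <- m$balance
  say("  %s: max |SMD| %.3f -> %.3f", cn,
      max(abs(bal$smd_before)), max(abs(bal$smd_after)))
}
balance <- do.call(rbind, lapply(names(matched), function(cn) {
  cbind(condition = cn, matched[[cn]]$balance)
}))
write.csv(balance, file.path(out_dir, "balance.csv"), row.names = FALSE)
say("balance table written to %s", file.path(out_dir, "balance.csv"))
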
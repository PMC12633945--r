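# Shared setup for the analysis drivers: one master seed, one output root.
# Override the seed with BRAINAGE_SEED, e.g. BRAINAGE_SEED=7 Rscript analysis/01_generate_cohort.R

library(brainagegap)

master_seed <- as.integer(Sys.getenv("BRAINAGE_SEED", "1"))
out_dir <- file.path("results", "analysis")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

say <- function(...) cat(sprintf(...), "\n")
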
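# Fit the reference brain-age model: split the cohort, select alpha by exact
# leave-one-out CV on a 5,000-subject healthy training sample, report healthy
# test MAE, and fit the sample-level bias correction on all test subjects.

source("analysis/00_common.R")

cohort <- load_cohort_csv(file.path(out_dir, "cohort.csv"),
                          file.path(out_dir, "cohort_truth.csv"))
sp <- split_cohort(cohort, test_fraction = 0.3, seed = master_seed)
say("training pool: %d healthy subjects; test pool: %d (of which %d patients)",
    nrow(sp$train$subjects), nrow(sp$test$subjects),
    sum(rowSums(sp$test$subjects[c("global_strong", "global_weak", "focal")]) > 0))

tr <- withr::with_seed(master_seed, sample.int(nrow(sp$train$subjects), 5000))
Xtr <- sp$train$features[tr, ]
ytr <- sp$train$subjects$age[tr]

sel <- select_alpha_cv(Xtr, ytr, alpha_grid(), method = "loo")
say("CV-selected alpha: %.3g (LOO mean squared error %.2f)",
    sel$best_alpha, min(sel$cv_error))

model <- fit_ridge(Xtr, ytr, sel$best_alpha)
write_model_json(model, file.path(out_dir, "brainage_model.json"))

preds <- predict_age(model, sp$test$features)
gaps <- make_gap_table(sp$test$subjects$subject_id, sp$test$subjects$age, preds)
corr <- fit_bias_correction(gaps)
print(corr)
gaps <- apply_bias_correction(gaps, corr)
write.csv(gaps, file.path(out_dir, "gap_table.csv"), row.names = FALSE)

healthy <- rowSums(sp$test$subjects[c("global_strong", "global_weak", "focal")]) == 0
say("healthy-test MAE: %.2f years (n = %d)",
    mean_absolute_error(sp$test$subjects$age[healthy], preds[healthy]),
    sum(healthy))
say("corrected-gap / age correlation: %.1e (orthogonal by construction)",
    cor(gaps$corrected_gap, gaps$age))
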
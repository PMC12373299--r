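#!/usr/bin/env Rscript

# Stage 3: balanced patient split, univariate selection, grid-searched
# main model.
#
# 70/30 patient-level split resampled until outcome prevalence and contact
# shares balance; baseline contacts removed from training; chi-square /
# Mann-Whitney selection at alpha = 0.05 on the training rows; grid search
# over ridge logistic regression, decision tree, random forest and
# gradient-boosted trees with patient-grouped 5-fold cross-validation
# selecting by AUC; decision cutoff from out-of-fold Youden's J.

suppressMessages(library(slecast))

cohort <- read_cohort("results/cohort")
labels <- label_cohort(cohort)
rows <- featurize_cohort(cohort, labels)

split <- split_patients(labels, seed = 2023)
train_ids <- split$assignment$patient_id[split$assignment$split == "train"]
train_rows <- drop_baseline_rows(rows[rows$patient_id %in% train_ids, ])
test_rows <- rows[!(rows$patient_id %in% train_ids), ]

selection <- select_features(train_rows, alpha = 0.05)
train_sel <- apply_selection(train_rows, selection)

model <- grid_search(train_sel, seed = 2024)
model$training_x <- as.data.frame(train_sel[, model$feature_names])

readr::write_csv(split$assignment, "results/split.csv")
readr::write_csv(selection, "results/selection.csv")
readr::write_csv(model$cv_table, "results/cv_table.csv")
saveRDS(list(model = model, split = split, rows = rows,
             train_rows = train_rows, train_sel = train_sel,
             test_rows = test_rows),
        "results/state_main.rds")

message(sprintf("split: %d train / %d test patients (attempt %d), prevalence gap %.3f",
                length(train_ids), sum(split$assignment$split == "test"),
                split$attempts, abs(split$prev_train - split$prev_test)))
message(sprintf("selected %d of %d features at alpha 0.05",
                sum(selection$selected), nrow(selection)))
message(sprintf("winner: %s (%s), cv AUC %.3f, cutoff %.3f",
                model$family,
                paste(names(model$params), unlist(model$params),
                      sep = "=", collapse = ","),
                model$cv_auc, model$cutoff))
message("wrote results/split.csv, results/selection.csv, results/cv_table.csv, results/state_main.rds")
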
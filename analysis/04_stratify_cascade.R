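#!/usr/bin/env Rscript

# Stage 4: risk stratification and the cascade rule model.
#
# Derives the strong/moderate/mild probability bands from the out-of-fold
# training predictions (TP quartiles above the cutoff, TN quartiles below),
# fits a bounded decision tree on the mild training contacts using only
# demographics and current treatments, extracts its decision paths as
# rules, and keeps the paths with training accuracy above 60%.

suppressMessages(library(slecast))

state <- readRDS("results/state_main.rds")
model <- state$model

thresholds <- fit_thresholds(model$oof, model$cutoff)
oof_strata <- stratify(model$oof, thresholds)
mild_train <- state$train_rows[oof_strata$confidence == "mild", ]

cascade <- fit_cascade(mild_train, feature_cols = cascade_feature_set(state$rows))
rules <- suppressWarnings(select_rules(cascade$rules, min_accuracy = 0.60))

readr::write_csv(
  tibble::tibble(threshold = c("cutoff", "tp_q1", "tp_median",
                               "tn_median", "tn_q3"),
                 value = c(thresholds$cutoff, thresholds$tp_q1,
                           thresholds$tp_median, thresholds$tn_median,
                           thresholds$tn_q3)),
  "results/risk_thresholds.csv")
rules_flat <- rules
rules_flat$predicates <- vapply(rules$predicates, function(p)
  paste(sprintf("%s %s %g", p$feature, p$op, p$threshold), collapse = " AND "),
  character(1))
readr::write_csv(rules_flat, "results/cascade_rules.csv")
saveRDS(list(thresholds = thresholds, oof_strata = oof_strata,
             cascade = cascade, rules = rules),
        "results/state_cascade.rds")

message(sprintf("training strata (out-of-fold): %s",
                paste(names(table(oof_strata$confidence)),
                      table(oof_strata$confidence),
                      sep = "=", collapse = ", ")))
message(sprintf("cascade: %d decision paths, %d kept above 60%% accuracy",
                nrow(cascade$rules), nrow(rules)))
for (i in seq_len(nrow(rules_flat))) {
  message(sprintf("  rule %d (%s, acc %.2f, n=%d): %s",
                  rules_flat$rule_id[i], rules_flat$predicted_risk[i],
                  rules_flat$accuracy[i], rules_flat$support[i],
                  rules_flat$predicates[i]))
}
message("wrote results/risk_thresholds.csv, results/cascade_rules.csv, results/state_cascade.rds")
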
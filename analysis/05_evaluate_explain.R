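#!/usr/bin/env Rscript

# Stage 5: hierarchical evaluation and Shapley explanation.
#
# Routes the test contacts through the hierarchical model (main model on
# strong/moderate, cascade rules on mild), evaluates AUC with patient-level
# bootstrap intervals on the five comparison subsets, and computes global
# and per-patient longitudinal Shapley attributions.

suppressMessages(library(slecast))

state <- readRDS("results/state_main.rds")
casc <- readRDS("results/state_cascade.rds")

hmodel <- hierarchical_model(state$model, casc$thresholds, casc$rules)
pred <- predict_hierarchical(hmodel, state$test_rows)
report <- evaluate_subsets(pred, n_boot = 500, seed = 2025)

att <- global_attribution(state$model, state$test_rows[1:200, ])
top <- head(att$attribution$feature_order, 10)
pid <- state$test_rows$patient_id[1]
long <- longitudinal_attribution(
  state$model, state$test_rows[state$test_rows$patient_id == pid, ])

readr::write_csv(pred, "results/test_predictions.csv", na = "")
readr::write_csv(report, "results/evaluation.csv")
readr::write_csv(att$beeswarm, "results/beeswarm.csv")
readr::write_csv(long$top_features, "results/longitudinal_attribution.csv")

message("subset evaluation (AUC [95% CI], n):")
for (i in seq_len(nrow(report))) {
  message(sprintf("  %-22s %.3f [%.3f, %.3f]  n=%d", report$subset[i],
                  report$auc[i], report$ci_low[i], report$ci_high[i],
                  report$n[i]))
}
message("top features by mean |attribution|: ", paste(top, collapse = ", "))
message(sprintf("longitudinal drill-down written for patient %s (%d contacts)",
                pid, nrow(long$per_contact)))
message("wrote results/test_predictions.csv, results/evaluation.csv, results/beeswarm.csv, results/longitudinal_attribution.csv")
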
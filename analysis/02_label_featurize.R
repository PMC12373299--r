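#!/usr/bin/env Rscript

# Stage 2: forward-window outcome labeling and feature engineering.
#
# Labels every contact with the composite 12-month activity outcome (NRV
# manifestation OR new organ involvement OR qualifying SLE hospitalization
# in the next 365 days) and builds the current / last-12-months / history
# feature blocks.

suppressMessages(library(slecast))

cohort <- read_cohort("results/cohort")
labels <- label_cohort(cohort)
rows <- featurize_cohort(cohort, labels)

labels_flat <- labels
labels_flat$triggering_events <- vapply(
  labels_flat$triggering_events,
  function(t) paste(sprintf("%s@%s", t$kind, t$date), collapse = ";"),
  character(1))
readr::write_csv(labels_flat, "results/labels.csv", na = "")
readr::write_csv(rows, "results/features.csv", na = "")

message(sprintf(
  "labeled %d contacts: prevalence %.1f%%, %.1f%% censored; %d features per contact",
  nrow(labels), 100 * prevalence(labels), 100 * mean(labels$censored),
  length(feature_columns(rows))))
message("wrote results/labels.csv, results/features.csv")
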
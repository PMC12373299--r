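#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic SLE cohort.
#
# Generates the default 300-patient longitudinal cohort (seed 1) and writes
# it as flat files under results/cohort/ together with the realized
# calibration report. The defaults emulate the data mart's printed
# marginals: ~88% female, median baseline age 43, median ~16 contacts over
# ~6 years, and ~48% contact-level positive outcome prevalence.

suppressMessages(library(slecast))

seed <- 1
gen <- generate_cohort(generator_config(n_patients = 300, seed = seed))

dir.create("results", showWarnings = FALSE)
write_cohort(gen$cohort, "results/cohort")
readr::write_csv(gen$report, "results/generator_report.csv")
readr::write_csv(cohort_summary(gen$cohort), "results/cohort_summary.csv")

message(sprintf(
  "simulated %d patients / %d contacts: %.0f%% female, median age %d, median %d contacts, prevalence %.1f%%",
  gen$report$n_patients, gen$report$n_contacts,
  100 * gen$report$female_fraction, gen$report$median_baseline_age,
  gen$report$median_contacts, 100 * gen$report$positive_prevalence))
message("wrote results/cohort/, results/generator_report.csv, results/cohort_summary.csv")
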
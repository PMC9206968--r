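#!/usr/bin/env Rscript

# Step 3 -- when do the subtypes become identifiable?
#
# For each visit, trains a fresh two-layer graph convolutional classifier
# on single-visit symptom-symptom graphs labeled with the full-trajectory
# subtypes from step 2, and records held-out accuracy -- for all patients
# and separately by treatment arm (10 seeded replicates per cell).
# High accuracy at a visit means subtype membership is already expressed
# in that visit's symptom configuration.

suppressPackageStartupMessages(library(tpcstroke))

cohort <- load_cohort("results/cohort.csv", "results/catalog.csv")
labels <- read.csv("results/labels.csv")
part <- run_tpc(cohort, kappa = 0.5, seed = 2024, n_restarts = 20,
                min_report_size = 10, verbose = FALSE)
stopifnot(identical(unname(part$labels[labels$patient]), labels$community))

curve <- stratification_analysis(cohort, part,
                                 slices = c("all", "treated", "placebo"),
                                 replicates = 10, seed = 7,
                                 epochs = 100, hidden_units = 64)
write.csv(curve, "results/accuracy.csv", row.names = FALSE, quote = FALSE)
print(curve)

all_curve <- curve[curve$cohort == "all", ]
peak <- all_curve$timepoint[which.max(all_curve$mean_accuracy)]
message("stratification is sharpest at visit ", peak,
        " (accuracy ", round(max(all_curve$mean_accuracy), 3), ")")
message("in this simulated cohort severity decays toward recovery, so the ",
        "subtypes are most visible at admission; late visits approach ",
        "chance as all archetypes converge to low severity")
message("wrote accuracy.csv to results/")
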
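#!/usr/bin/env Rscript
# Build the synthetic study cohort: 21 patients, 5 resection-margin scans
# each, six histology classes, 60% of scans carrying fold-over or dropout
# artifacts. Writes the per-scan plan (labels + ground truth) and one
# example volume so the on-disk formats are exercised.

library(octmargin)

dir.create("results", showWarnings = FALSE)
spec <- cohort_spec(seed = 1L)
params <- default_tissue_params()
system <- oct_system()

plan <- cohort_plan(spec, params)
write_label_table(plan[, c("patient_id", "scan_id", "label", "artifact")],
                  "results/cohort_labels.csv")
write_label_table(plan[, c("patient_id", "scan_id", "label", "mu",
                           "intensity_db", "artifact")],
                  "results/cohort_truth.csv")

example <- materialize_scan(plan[1, ], spec, params, system)
write_oct_volume(example, "results/example_volume")

message(sprintf("cohort: %d scans over %d patients", nrow(plan),
                length(unique(plan$patient_id))))
message(sprintf("label mix: %s",
                paste(names(table(plan$label)), table(plan$label),
                      sep = "=", collapse = ", ")))
message(sprintf("artifacts injected: %d (%.0f%%)",
                sum(plan$artifact != "none"),
                100 * mean(plan$artifact != "none")))
message("wrote results/cohort_labels.csv, results/cohort_truth.csv, ",
        "results/example_volume.{tiff,json}")
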
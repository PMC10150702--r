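#!/usr/bin/env Rscript
# Visual classification against histology: the joint agreement matrix,
# binarized diagnostic metrics of the automated grader, and inter-observer
# concordance between two grader configurations (a second observer is
# emulated by shifting the qualitative decision thresholds).

library(octmargin)

visual <- read_label_table("results/visual.csv")

heat <- agreement_heatmap(visual$visual_class, visual$label)
write.csv(heat, "results/agreement_heatmap.csv")
print(heat)

# binarized diagnostic accuracy against the infiltration ground truth
truth_tumor <- visual$label %in% c("WM0_30", "WM30_60", "WM60plus")
pred_tumor <- binarize_visual(visual$visual_class) == "tumor"
m <- compute_metrics(tp = sum(pred_tumor & truth_tumor),
                     fp = sum(pred_tumor & !truth_tumor),
                     tn = sum(!pred_tumor & !truth_tumor),
                     fn = sum(!pred_tumor & truth_tumor))
message(sprintf(
  "automated grader vs histology: sens %.0f%% spec %.0f%% bal acc %.0f%%",
  m$sensitivity, m$specificity, m$balanced_accuracy))

# second observer: same scans, shifted thresholds (stricter intensity,
# laxer homogeneity), then concordance
spec <- cohort_spec(seed = 1L)
params <- default_tissue_params()
system <- oct_system()
plan <- cohort_plan(spec, params)
obs2 <- character(0)
kept <- paste(visual$patient_id, visual$scan_id)
for (i in seq_len(nrow(plan))) {
  if (!paste(plan$patient_id[i], plan$scan_id[i]) %in% kept) next
  vol <- materialize_scan(plan[i, ], spec, params, system)
  pre <- preprocess_scan(vol)
  cr <- grade_criteria(pre$volume, intensity_db = 57,
                       homogeneity_cv = 0.18, uniformity_sd_um = 90)
  obs2 <- c(obs2, classify_visual(cr))
}
agree <- observer_agreement(visual$visual_class, obs2)
message(sprintf("inter-observer agreement %.0f%%, Cohen's kappa %.2f",
                100 * agree$observed_agreement, agree$kappa))
write.csv(as.data.frame.matrix(agree$table),
          "results/observer_agreement.csv")
message("wrote results/agreement_heatmap.csv, results/observer_agreement.csv")
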
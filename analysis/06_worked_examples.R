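#!/usr/bin/env Rscript
# Diagnostic arithmetic on the bundled clinical count tables: sensitivity
# and accuracy of fluorescein-sodium guidance and early post-operative MRI
# from the patient-level contingencies, and balanced accuracies from the
# published sensitivity/specificity operating points.

library(octmargin)

dir.create("results", showWarnings = FALSE)
we <- worked_examples()

for (study in names(we$contingency)) {
  m <- we$contingency[[study]]
  message(sprintf(
    "%s: tp=%d fp=%d tn=%d fn=%d -> sensitivity %d%%, accuracy %d%%",
    study, m$counts[["tp"]], m$counts[["fp"]], m$counts[["tn"]],
    m$counts[["fn"]], m$sensitivity_rounded, m$accuracy_rounded))
}

op <- we$operating_points
print(op, row.names = FALSE)
write_label_table(op, "results/worked_examples.csv")
message("wrote results/worked_examples.csv")
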
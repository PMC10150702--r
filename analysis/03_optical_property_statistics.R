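#!/usr/bin/env Rscript
# Group statistics over the fitted optical properties: per-class medians
# and quartiles, Shapiro-Wilk normality, pairwise Wilcoxon rank-sum tests
# with significance stars, and the attenuation comparisons against healthy
# white matter.

library(octmargin)

props <- read_label_table("results/properties.csv")

summ <- do.call(rbind, lapply(split(props, props$label), function(d) {
  data.frame(
    label = d$label[1], n = nrow(d),
    mu_median = median(d$mu),
    mu_q25 = quantile(d$mu, 0.25), mu_q75 = quantile(d$mu, 0.75),
    I_db_median = median(d$I_db),
    r2_median = median(d$r2)
  )
}))
write_label_table(summ, "results/property_summary.csv")
print(summ, row.names = FALSE)

for (prop in c("mu", "I_db", "r2")) {
  st <- compare_groups(props[[prop]], props$label)
  write_label_table(st$pairwise, sprintf("results/stats_%s.csv", prop))
  n_sig <- sum(st$pairwise$stars != "", na.rm = TRUE)
  message(sprintf("%s: %d/%d pairwise comparisons significant at 0.05",
                  prop, n_sig, nrow(st$pairwise)))
}

wm <- summ$mu_median[summ$label == "WM0"]
message(sprintf("gray matter attenuation %.0f%% lower than healthy WM",
                100 * (1 - summ$mu_median[summ$label == "GM0"] / wm)))
message(sprintf("edematous WM attenuation %.0f%% lower than healthy WM",
                100 * (1 - summ$mu_median[summ$label == "WME"] / wm)))
message("wrote results/property_summary.csv and results/stats_*.csv")
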
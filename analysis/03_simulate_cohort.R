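#!/usr/bin/env Rscript
# Step 3: simulate the three-group cohort (healthy controls, hypertensives
# without heart failure, hypertensives with heart failure) with FD, LV
# function and demographics drawn from the published group means/SDs, and
# write it as the cohort CSV consumed by the statistical steps.

suppressMessages(library(trabfd))
dir.create("results", showWarnings = FALSE)

tab <- generate_synthetic_cohort(cohort_sim_spec(seed = 42L))
write.csv(tab, "results/cohort.csv", row.names = FALSE)

cat("Simulated cohort:", nrow(tab), "subjects\n")
print(table(tab$group))
cat("\nGlobal FD by group (mean +/- SD):\n")
for (g in levels(tab$group)) {
  v <- tab$fd_global[tab$group == g]
  cat(sprintf("  %-10s %.3f +/- %.3f (n = %d)\n", g, mean(v), sd(v),
              length(v)))
}
cat(sprintf("\nPooled Spearman correlation FD-global vs maximal LVWT: %.2f\n",
            cor(tab$fd_global, tab$max_lvwt, method = "spearman")))
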
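#!/usr/bin/env Rscript
# Step 4: baseline-characteristics analysis of the simulated cohort --
# three-group comparisons with normality-gated test choice, ANCOVA
# adjustment (age, sex) for the FD summaries, and the Spearman correlation
# matrix of FD against LV function and clinical covariates.

suppressMessages(library(trabfd))
tab <- read.csv("results/cohort.csv", stringsAsFactors = TRUE)
tab$group <- factor(tab$group, levels = c("control", "HTN_nonHF", "HTN_HF"))

report <- run_cohort(tab)

cmp <- comparison_table(report)
write.csv(cmp, "results/group_comparisons.csv", row.names = FALSE)
corr <- report$correlations
write.csv(round(corr$rho, 3), "results/fd_correlations_rho.csv")
write.csv(signif(corr$p, 3), "results/fd_correlations_p.csv")

fd_rows <- cmp[grepl("^fd_", cmp$variable), ]
cat("FD summaries across the three groups:\n")
print(fd_rows, row.names = FALSE, digits = 3)
omni <- fd_rows$variable[fd_rows$p < 0.05]
adj <- fd_rows$variable[!is.na(fd_rows$ancova_p) & fd_rows$ancova_p < 0.05]
pw <- fd_rows$variable[fd_rows$pairwise_hf_vs_nonhf >= 0.05]
cat(sprintf("\n%d/5 FD summaries separate the three groups (omnibus p < 0.05); %d/5 survive age/sex adjustment.\n",
            length(omni), length(adj)))
if (length(pw)) {
  cat("Not discriminating HF from non-HF hypertensives in this cohort draw:",
      paste(pw, collapse = ", "), "\n")
} else {
  cat("In this cohort draw every FD summary also separates the two",
      "hypertensive groups pairwise; across repeated draws maximal basal FD",
      "is the summary that most often fails to (its group means differ",
      "least).\n")
}
cat(sprintf("\nFD vs maximal LVWT rank correlations: %s\n",
            paste(sprintf("%.2f", corr$rho[, "max_lvwt"]), collapse = ", ")))
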
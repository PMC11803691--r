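#!/usr/bin/env Rscript

# Run the full GA-adjusted statistical analysis on the simulated cohort:
# demographics, GA correlations, ANCOVA/ANOVA group comparisons with BH
# correction, and GA-partialled brain-placenta correlations.

suppressPackageStartupMessages(library(placentaflow))

tab <- read_cohort_table("results/cohort/cohort.csv")
report <- run_statistics(tab)
write_stats_report(report, "results/cohort")

cat("group comparisons (GA-adjusted where planned):\n")
print(report$group_comparisons, digits = 3)
cat("\npartial correlations (GA-partialled):\n")
print(report$partial_correlations, digits = 3)
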
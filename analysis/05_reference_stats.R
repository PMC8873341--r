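#!/usr/bin/env Rscript
# Step 5 — reproduce the published statistical analysis.
#
# Runs the statistics stage on the packaged reference accuracy tables
# (10 control and 10 baseline subjects, budgets 10..60) and prints the
# recomputed numbers next to the published ones: per-budget group means,
# Shapiro-Wilk normality of every column, the two-tailed paired t-test on
# the budget-60 columns, the mean paired difference and the table maximum.

suppressPackageStartupMessages(library(fnirstransfer))

dir.create("results", showWarnings = FALSE)

report <- reproduce_reference_stats()
print(report)
report_to_json(report, "results/05_reference_stat_report.json")
cat("\nFull report -> results/05_reference_stat_report.json\n")
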
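#!/usr/bin/env Rscript
# Base-case cost-utility analysis: discounted costs and QALYs per arm and
# incremental cost-effectiveness ratios over 5/10/15-year horizons for the
# two response-utility elicitations (0.79 time trade-off, 0.82 visual
# rating scale). Writes results/base_case_arms.csv and results/icer_table.csv.

suppressPackageStartupMessages(library(uccea))

arms <- do.call(rbind, lapply(c(5, 10, 15), function(h)
  rbind(arm_summary(analysis_request(h, 0.79)),
        arm_summary(analysis_request(h, 0.82)))))
write_results_csv(arms, "results/base_case_arms.csv")

cat("10-year base case (utility 0.79):\n")
print(subset(arms, horizon_years == 10 & response_utility == 0.79,
             c(arm, cost_reported, qalys_reported)), row.names = FALSE)

cat("\nICER grid with one-way sensitivity ranges (rounded to $1,000):\n")
tab <- make_table1("base")
format_icer_table(tab)
write_results_csv(tab, "results/icer_table.csv")

cat("\nThe ratio rises with the horizon because drug costs keep accruing",
    "\nwhile the QALY gain concentrates in the early response years;",
    "\nthe 0.82 elicitation gives a larger QALY gain, hence lower ratios.\n")
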
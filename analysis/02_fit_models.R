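#!/usr/bin/env Rscript

# Stage 2: fit the nested model families with leave-one-out cross-validation
# and assemble the comparison grid.
#
# Families: full lesion-load models (LLV), reductions without lesion location
# (reduced_no_llv) and without location or extent (reduced_no_llv_no_extent),
# plus LLV + initial presentation (llv_ip) for the overall score at the
# follow-up timepoints. Every cell is a fresh leave-one-out run; predictions
# are capped to the 0-10 score range and scored with prediction r^2 and RMSE.

library(mlsm)

cohort <- load_cohort("results/cohort")
dir.create("results", showWarnings = FALSE)

grid_main <- build_comparison_grid(
  cohort, families = c("llv", "reduced_no_llv"),
  outcomes = mlsm_outcomes(), timepoints = mlsm_timepoints(),
  keep_predictions = TRUE, verbose = TRUE)

grid_extra <- build_comparison_grid(
  cohort, families = "reduced_no_llv_no_extent",
  outcomes = "overall", timepoints = mlsm_timepoints())

grid_ip <- build_comparison_grid(
  cohort, families = c("llv_ip", "reduced_no_llv_ip"),
  outcomes = "overall", timepoints = c("1mo", "3mo", "12mo"))

grid <- rbind(grid_main, grid_extra, grid_ip)
write.table(grid, "results/comparison_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")
write.table(attr(grid_main, "predictions"), "results/predictions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nOverall-score prediction r^2 by family and timepoint:\n")
ov <- grid[grid$outcome == "overall" & grid$status == "ok", ]
print(reshape(ov[c("family", "timepoint", "prediction_r2")],
              idvar = "family", timevar = "timepoint", direction = "wide"),
      row.names = FALSE, digits = 3)

imp <- improvement_count(grid_main)
cat(sprintf("\nLesion location (LLV) improved prediction in %d of %d cells\n",
            imp$improved, imp$total))
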
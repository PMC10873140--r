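#!/usr/bin/env Rscript

# Stage 4: figures from the serialized tables (no hidden state: everything is
# regenerable from results/*.tsv alone).

library(ggplot2)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

grid <- read.delim("results/comparison_grid.tsv")
grid <- grid[grid$status == "ok", ]
grid$timepoint <- factor(grid$timepoint, c("acute", "1mo", "3mo", "12mo"))

p1 <- ggplot(grid[grid$outcome == "overall", ],
             aes(timepoint, prediction_r2, fill = family)) +
  geom_col(position = position_dodge(width = 0.8), width = 0.7,
           colour = "grey20") +
  scale_fill_brewer(palette = "Blues") +
  labs(y = expression(prediction ~ r^2), x = NULL,
       title = "Overall language score: nested model families") +
  theme_minimal()
ggsave("results/figures/overall_r2_by_family.png", p1,
       width = 7, height = 4, dpi = 150)

llv <- grid[grid$family == "llv", ]
p2 <- ggplot(llv, aes(timepoint, prediction_r2)) +
  geom_col(fill = "steelblue", colour = "grey20", width = 0.7) +
  facet_wrap(~outcome) +
  labs(y = expression(prediction ~ r^2), x = NULL,
       title = "Lesion-load models across language domains") +
  theme_minimal()
ggsave("results/figures/llv_r2_by_outcome.png", p2,
       width = 9, height = 7, dpi = 150)

preds <- read.delim("results/predictions.tsv")
ov12 <- preds[preds$outcome == "overall" & preds$timepoint == "12mo" &
                preds$family == "llv", ]
p3 <- ggplot(ov12, aes(predicted, observed)) +
  geom_abline(colour = "grey60") +
  geom_point(alpha = 0.6) +
  coord_fixed(xlim = c(0, 10), ylim = c(0, 10)) +
  labs(x = "Predicted overall score", y = "Observed overall score",
       title = "Out-of-sample predictions, 1-year timepoint (LLV model)") +
  theme_minimal()
ggsave("results/figures/observed_vs_predicted_12mo.png", p3,
       width = 5, height = 5, dpi = 150)

cat("Figures written to results/figures/\n")
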
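#!/usr/bin/env Rscript
# Step 6 — rank models by the Global Performance Indicator.
#
# Normalizes R2, RMSE and MAE per cultivar over all models x iterations,
# sums the signed deviations from the pooled medians (alpha = -1 for R2,
# +1 for the errors) and ranks models within each cultivar; the model of
# the max-FI candidate is flagged. Output: results/ranking.csv.

suppressPackageStartupMessages(library(oleohyst))

metrics <- read.csv("results/metrics.csv")
sel <- read.csv("results/selection.csv")

max_fi <- vapply(split(sel, sel$cultivar), function(s)
  s$ci_name[which.max(s$fi)], character(1))
ranking <- rank_models(gpi(normalize_metrics(metrics)),
                       max_fi_model = max_fi)
write.csv(ranking, "results/ranking.csv", row.names = FALSE)

for (cu in unique(ranking$cultivar)) {
  rk <- ranking[ranking$cultivar == cu, ]
  top <- head(rk, 3)
  cat(sprintf("%-10s top: %s   max-FI model %s at rank %d\n", cu,
              paste(sprintf("%s (GPI %.2f)", top$model_id, top$gpi),
                    collapse = ", "),
              rk$model_id[rk$is_max_fi][1], rk$rank[rk$is_max_fi][1]))
}
conc <- sum(ranking$rank[ranking$is_max_fi] <= 2)
cat(sprintf("\nFI/GPI concordance: max-FI model in the GPI top 2 in %d of %d cultivars\n",
            conc, length(unique(ranking$cultivar))))
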
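#!/usr/bin/env Rscript
# Step 5 — fit and evaluate the oil-prediction models.
#
# Per cultivar: the full oil ~ red + green + blue model, a VIF-reduced
# version where collinearity (VIF > 5) requires it, and one
# single-predictor model per selected candidate, all on the same
# benchmark 70/30 split plan repeated five times.
# Outputs: results/metrics.csv, results/residuals.csv.

suppressPackageStartupMessages(library(oleohyst))
SEED <- 1

itab <- read.csv("results/index_table.csv")
sel <- read.csv("results/selection.csv")

metrics <- list(); resids <- list()
for (cu in unique(itab$cultivar)) {
  sub <- itab[itab$cultivar == cu, ]
  sub <- sub[order(sub$date_index, sub$replicate), ]
  chosen <- sel$ci_name[sel$cultivar == cu & sel$selected]
  plan <- make_splits(nrow(sub), seed = SEED * 977 + match(cu, unique(itab$cultivar)))
  suite <- run_model_suite(sub, chosen, plan)
  suite$metrics <- cbind(cultivar = cu, suite$metrics)
  suite$residuals <- cbind(cultivar = cu, suite$residuals)
  metrics[[cu]] <- suite$metrics
  resids[[cu]] <- suite$residuals
  rgb_r2 <- median(suite$metrics$r2[suite$metrics$model_id == "RGB"])
  red_flag <- if ("RGB_reduced" %in% suite$metrics$model_id)
    sprintf(" (collinearity: reduced to %s)",
            suite$metrics$predictors[suite$metrics$model_id == "RGB_reduced"][1])
  else ""
  cat(sprintf("%-10s %d models x %d iterations; RGB median R2 = %.2f%s\n",
              cu, length(unique(suite$metrics$model_id)),
              plan$n_iterations, rgb_r2, red_flag))
}
metrics <- do.call(rbind, metrics); rownames(metrics) <- NULL
resids <- do.call(rbind, resids); rownames(resids) <- NULL
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
write.csv(resids, "results/residuals.csv", row.names = FALSE)

pool <- aggregate(residual ~ cultivar, resids, function(r)
  c(mean = mean(r), sd = sd(r)))
cat("\npooled test residuals (should centre on 0):\n")
print(data.frame(cultivar = pool$cultivar, round(pool$residual, 3)),
      row.names = FALSE)
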
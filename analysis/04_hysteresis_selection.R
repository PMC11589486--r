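#!/usr/bin/env Rscript
# Step 4 — quantify hysteresis and select predictors.
#
# For every (cultivar, candidate) pair: Hyst (loop-area index), Spearman
# rho and the Fitness Index FI = |Hyst| + |rho|; candidates in the top
# FI quintile become model predictors. Candidates are the 35 indexes
# plus the three raw bands. Output: results/selection.csv.

suppressPackageStartupMessages(library(oleohyst))

itab <- read.csv("results/index_table.csv")
sel_all <- do.call(rbind, lapply(split(itab, itab$cultivar), function(sub) {
  sub <- sub[order(sub$date_index, sub$replicate), ]
  sel <- select_predictors(score_predictors(sub))
  cbind(cultivar = sub$cultivar[1], sel,
        fi_threshold = attr(sel, "fi_threshold"))
}))
rownames(sel_all) <- NULL
write.csv(sel_all, "results/selection.csv", row.names = FALSE)

for (cu in unique(sel_all$cultivar)) {
  s <- sel_all[sel_all$cultivar == cu & sel_all$selected, ]
  s <- s[order(-s$fi), ]
  cat(sprintf("%-10s FI quintile %4.2f:%4.2f  selected: %s\n", cu,
              min(s$fi), max(s$fi), paste(s$ci_name, collapse = ", ")))
}
cat(sprintf("\n%d of %d (cultivar, candidate) pairs selected\n",
            sum(sel_all$selected), nrow(sel_all)))
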
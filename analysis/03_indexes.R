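#!/usr/bin/env Rscript
# Step 3 — compute the 35 colorimetric indexes per sample.
#
# Joins each cultivar's band means to its oil record and evaluates the
# index registry. Output: results/index_table.csv (all cultivars).

suppressPackageStartupMessages(library(oleohyst))

files <- list.files("results", pattern = "^season_.*\\.csv$",
                    full.names = TRUE)
stopifnot(length(files) == 6)
tabs <- lapply(files, function(f) {
  s <- read_season_csv(f)
  cbind(s, compute_indexes(s$red, s$green, s$blue))
})
itab <- do.call(rbind, tabs)
write.csv(itab, "results/index_table.csv", row.names = FALSE)

n_undef <- sum(is.na(itab[, names(ci_registry())]))
cat(sprintf("index table: %d rows x %d columns (%d undefined CI cells)\n",
            nrow(itab), ncol(itab), n_undef))
cat("normalized band example (green px per %FW, Arbequina):",
    round(head(normalize_by_oil(itab$green[itab$cultivar == "Arbequina"],
                                itab$oil[itab$cultivar == "Arbequina"]), 3), 2),
    "...\n")
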
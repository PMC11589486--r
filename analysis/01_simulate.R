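#!/usr/bin/env Rscript
# Step 1 — simulate the six-cultivar season dataset.
#
# Generates the synthetic seasonal tables (oil %FW + mean R/G/B per
# replicate sample) for Arbequina, Fasola, Frantoio, Koroneiki, Leccino
# and Maiatica, plus a small set of rendered image fixtures for the
# imaging step. Outputs: results/season_<cultivar>.csv, results/fixtures/.

suppressPackageStartupMessages(library(oleohyst))
SEED <- 1
dir.create("results/fixtures", recursive = TRUE, showWarnings = FALSE)

cfg <- default_cultivar_params()
ds <- generate_dataset(cfg, seed = SEED)

for (nm in names(ds$seasons)) {
  tab <- ds$seasons[[nm]]
  write_season_csv(tab, file.path("results", sprintf("season_%s.csv", nm)))
  cat(sprintf("%-10s %2d rows  oil %4.1f -> %4.1f %%FW   green %5.1f -> %5.1f px\n",
              nm, nrow(tab), tab$oil[1], tail(tab$oil, 1),
              tab$green[1], tail(tab$green, 1)))
}

# image fixtures for one cultivar's first 2 dates (keeps step 2 fast);
# each fixture's foreground mean is the table's band triple
tab <- ds$seasons$Arbequina
rows <- which(tab$date_index < 2)
manifest <- list()
for (r in rows) {
  fx <- render_sample_image(as.numeric(tab[r, c("red", "green", "blue")]),
                            n_fruits = 40, seed = SEED * 100 + r,
                            width = 320, height = 240)
  id <- sprintf("Arbequina_d%02d_r%d", tab$date_index[r], tab$replicate[r])
  write_fixture_png(fx, file.path("results/fixtures", paste0(id, ".png")),
                    file.path("results/fixtures", paste0("mask_", id, ".png")))
  manifest[[id]] <- list(target_rgb = fx$target_rgb,
                         true_mean_rgb = fx$true_mean_rgb,
                         n_fruits = fx$n_fruits)
}
jsonlite::write_json(manifest, "results/fixtures/fixtures.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("rendered %d Arbequina fixtures (+masks) under results/fixtures/\n",
            length(rows)))
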
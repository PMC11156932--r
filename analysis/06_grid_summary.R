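#!/usr/bin/env Rscript
# Step 6 — spatial summary: each eddy is placed at the mean position of its
# inside profiles and binned on a 3-degree grid; per cell, the percentage of
# eddies with a significant epipelagic NASC effect (increase + decrease),
# plus the latitudinal marginal.
#
#   Rscript analysis/06_grid_summary.R

suppressMessages(library(eddyforage))

profiles <- read_profiles_csv(file.path("results", "prepared_profiles.csv"))
collocation <- readr::read_csv(file.path("results", "collocation.csv"),
                               show_col_types = FALSE)
classification <- readr::read_csv(file.path("results", "classification.csv"),
                                  show_col_types = FALSE)

positions <- eddy_positions(profiles, collocation)
epi <- classification[classification$variable == "nasc_epipelagic", ]
grid <- summarize_grid(epi, positions, cell_degrees = 3)

write_table_csv(grid$cells, file.path("results", "grid_cells.csv"))
write_table_csv(grid$latitudinal, file.path("results", "grid_latitudinal.csv"))

cat(sprintf("Gridded %d eddies into %d occupied 3-degree cells.\n",
            sum(grid$cells$n_eddies), nrow(grid$cells)))
for (i in seq_len(nrow(grid$cells))) {
  with(grid$cells[i, ], cat(sprintf(
    "  cell [%g, %g): %d eddies, %.0f%% significant\n",
    lon_bin, lat_bin, n_eddies, pct_significant)))
}
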
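#!/usr/bin/env Rscript
# Step 1 — simulate the study world: an eddy atlas with known ground-truth
# effects, a survey track routed through the eddies, and the acoustic +
# surface samples collected along it. Writes the raw inputs every later
# step consumes.
#
#   Rscript analysis/01_simulate.R [--seed 42]

suppressMessages(library(eddyforage))

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[which(args == "--seed") + 1])
} else 42L

out <- file.path("results", "synthetic")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed, n_eddies = 8,
                        fraction_effect_eddies = 0.25,
                        effect_size_nasc = 1.5, noise_cv = 0.3,
                        profiles_per_track_km = 0.4)
sim <- generate_eddy_atlas(cfg)
cfg$track_plan <- plan_track_through_eddies(sim$atlas, as.Date(cfg$start_time))
track <- generate_track(cfg)
gen <- generate_profiles(track, sim$atlas, sim$truth, cfg)

write_atlas(sim$atlas, file.path(out, "atlas.csv"))
write_table_csv(sim$truth, file.path(out, "ground_truth.csv"))
write_table_csv(track, file.path(out, "track.csv"))
write_profiles_csv(gen$profiles, file.path(out, "profiles.csv"))

cat(sprintf(
  "Simulated %d eddies (%d with a x%.2f inside NASC effect), %d atlas records.\n",
  cfg$n_eddies, sum(sim$truth$has_nasc_effect), cfg$effect_size_nasc,
  nrow(sim$atlas)))
cat(sprintf(
  "Survey: %.0f km of track, %d profiles (%s to %s), noise CV %.2f.\n",
  max(track$dist_km), nrow(track),
  format(min(track$time), "%Y-%m-%d"), format(max(track$time), "%Y-%m-%d"),
  cfg$noise_cv))
cat("Wrote", out, "\n")
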
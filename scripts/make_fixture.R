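#!/usr/bin/env Rscript
# Regenerates the packaged synthetic fixture bundle and its golden pipeline
# outputs under inst/extdata/. Run from the repository root after any change
# that intentionally alters pipeline output formats:
#   Rscript scripts/make_fixture.R
# Everything here is synthetic (generated by the package's own generator);
# the bundle exists so the end-to-end determinism test has a fixed input and
# reference output to compare bytes against.

library(eddyforage)

fixture_dir <- file.path("inst", "extdata", "synthetic_fixture")
golden_dir <- file.path("inst", "extdata", "golden")
dir.create(fixture_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(golden_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(
  seed = 42, n_eddies = 3,
  lon_range = c(-32, -14), lat_range = c(-38, -26),
  radius_range = c(50, 70), lifespan_range = c(20, 30),
  fraction_effect_eddies = 1 / 3, effect_size_nasc = 1.5,
  noise_cv = 0.3, profiles_per_track_km = 0.05, ship_speed = 30
)
sim <- generate_eddy_atlas(cfg)
cfg$track_plan <- plan_track_through_eddies(sim$atlas, as.Date(cfg$start_time),
                                            overshoot_km = 200)
track <- generate_track(cfg)
gen <- generate_profiles(track, sim$atlas, sim$truth, cfg)

# keep only the atlas days the survey (plus the trapping window) touches
survey_dates <- range(as.Date(track$time))
atlas_out <- sim$atlas[sim$atlas$date >= survey_dates[1] - 2 &
                         sim$atlas$date <= survey_dates[2] + 2, ]
profiles_out <- gen$profiles
num_cols <- c("sst", "chl", nasc_bin_cols())
for (cc in num_cols) profiles_out[[cc]] <- signif(profiles_out[[cc]], 6)

write_atlas(atlas_out, file.path(fixture_dir, "atlas.csv"))
write_profiles_csv(profiles_out, file.path(fixture_dir, "profiles.csv"))

pcfg <- pipeline_config(synthetic = NULL,
                        atlas_path = file.path(fixture_dir, "atlas.csv"),
                        profiles_path = file.path(fixture_dir, "profiles.csv"))
res <- run_pipeline(pcfg)
write_pipeline_outputs(res, golden_dir)
print(res$manifest)
cat("fixture bytes:",
    sum(file.size(list.files(fixture_dir, full.names = TRUE))), "fixture /",
    sum(file.size(list.files(golden_dir, full.names = TRUE))), "golden\n")
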
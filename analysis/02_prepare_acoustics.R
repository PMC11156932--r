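#!/usr/bin/env Rscript
# Step 2 — acoustic preparation: label each profile day/night/twilight from
# its solar elevation, drop twilight profiles (diel vertical migration is in
# transit) and continental-shelf profiles (seabed < 1000 m).
#
#   Rscript analysis/02_prepare_acoustics.R

suppressMessages(library(eddyforage))

profiles <- read_profiles_csv(file.path("results", "synthetic", "profiles.csv"))
prepared <- prepare_profiles(profiles)
counts <- attr(prepared, "filter_counts")

write_profiles_csv(prepared, file.path("results", "prepared_profiles.csv"))

cat(sprintf(
  "Prepared %d of %d profiles: removed %d twilight and %d shelf profiles.\n",
  counts["retained"], counts["input"], counts["twilight_removed"],
  counts["shelf_removed"]))
cat(sprintf("Day/night split: %d day, %d night.\n",
            sum(prepared$period == "day"), sum(prepared$period == "night")))
cat("Wrote results/prepared_profiles.csv\n")
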
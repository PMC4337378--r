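#!/usr/bin/env Rscript

# Stage 2 — daily movement characteristics and day-stops.
#
# Reads the raw track tables, interpolates missing fixes onto the 10-min
# grid, computes the per-day metrics (activity, departure, travel
# distance, displacement, straightness, speed, elevation) and detects
# ground stops with their behaviour-label tallies.

suppressMessages(library(fdpscan))

in_dir <- "results/tracks"
fixes <- read_fix_table(file.path(in_dir, "fixes.csv"))
behaviors <- read_behavior_table(file.path(in_dir, "behaviors.csv"))
sunrise <- read_sunrise_table(file.path(in_dir, "sunrise.csv"))

message(sprintf("processing %d fixes into daily metrics ...", nrow(fixes)))
tracks <- process_tracks(fixes, behaviors, sunrise, run_config())

m <- tracks$metrics
ok <- !m$missing_day
act <- ok & m$active %in% TRUE
message(sprintf("  %d animal-days, %.1f%% active", sum(ok),
                100 * mean(m$active[ok])))
message(sprintf("  mean active-day straightness %.3f; departure %.2f h",
                mean(m$straightness[act], na.rm = TRUE),
                mean(m$departure_offset[act & !m$departure_censored],
                     na.rm = TRUE)))
message(sprintf("  %d day-stops detected", nrow(tracks$stops)))

dir.create("results", showWarnings = FALSE)
write.csv(m, "results/daily_metrics.csv", row.names = FALSE)
write.csv(tracks$stops, "results/day_stops.csv", row.names = FALSE)
message("wrote results/daily_metrics.csv and results/day_stops.csv")
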
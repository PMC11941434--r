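#!/usr/bin/env Rscript
# Simulate two synthetic matches under the default study conditions and write
# them in the tracking/event CSV dialect, as a worked example of the data the
# pipeline consumes. Larger experiments (scripts 03-04) simulate in memory.

library(emergentpitch)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- synthetic_params()
for (m in 1:2) {
  match <- generate_match(params, seed = 1000 + m)
  write_tracking(match$tracking, file.path(out, sprintf("match%02d_tracking.csv", m)))
  write_events(match$events, file.path(out, sprintf("match%02d_events.csv", m)),
               file.path(out, sprintf("match%02d_possession.csv", m)))
  ev <- match$events$events
  hb <- match$events$half_bounds
  cat(sprintf("match %d: %d frames, %d shots (%d home / %d away), home possession %.2f / %.2f\n",
              m, length(unique(match$tracking$frames$t)),
              sum(ev$event_type == "shot"),
              sum(ev$event_type == "shot" & ev$team == "home"),
              sum(ev$event_type == "shot" & ev$team == "away"),
              possession_rate(match$events, hb[1, ], "home"),
              possession_rate(match$events, hb[2, ], "home")))
}
cat("wrote", length(list.files(out)), "files under", out, "\n")
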
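#!/usr/bin/env Rscript
# Compute the sliding-window causal-emergence series Psi for all four
# macroscopic features of match 1 (written by 01_simulate_matches.R) and
# summarise the half-level means per team.

library(emergentpitch)

tp <- "results/data/match01_tracking.csv"
ep <- "results/data/match01_events.csv"
if (!file.exists(tp)) stop("run analysis/01_simulate_matches.R first")

events <- load_events(ep, "results/data/match01_possession.csv")
tracking <- load_tracking(tp, half_bounds = events$half_bounds, margin = 100)
dir.create("results/psi", recursive = TRUE, showWarnings = FALSE)

cat("half-level mean Psi (nats), 60-s windows, lag 1:\n")
cat(sprintf("%-18s %8s %8s %8s %8s\n", "feature", "home.h1", "home.h2",
            "away.h1", "away.h2"))
for (feat in c("com", "relative_distance", "clust_vel", "clust_dist")) {
  row <- c()
  for (team in c("home", "away")) {
    psi <- match_psi(tracking, events, team, feat)
    utils::write.csv(as.data.frame(psi),
                     sprintf("results/psi/match01_%s_%s.csv", feat, team),
                     row.names = FALSE)
    row <- c(row, vapply(1:2, function(h)
      half_mean_psi(psi, events$half_bounds[h, ]), 0))
  }
  cat(sprintf("%-18s %8.3f %8.3f %8.3f %8.3f\n", feat,
              row[1], row[2], row[3], row[4]))
}
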
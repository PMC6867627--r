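#!/usr/bin/env Rscript

# Stage 2: run the motility analysis on the tracks from stage 1.
#
# For each condition: project/unwrap is already done (tracks store phi),
# classify run and rest states, fit the dwell-time survival curves on
# [2, 16] h, and assemble the five-parameter fingerprint. Writes, per
# condition: fingerprint JSON, per-cell parameter table, segment table.

suppressPackageStartupMessages(library(ringlane))

geom <- ring_geometry(0, 0, 75)

for (cond in c("ctrl", "induced")) {
  tracks <- file.path("results", paste0("tracks_", cond, ".csv"))
  if (!file.exists(tracks)) stop("run analysis/01_simulate.R first: missing ", tracks)
  coll <- read_trajectories(tracks, geom,
                            dialect = trajectory_dialect(phi = "phi_rad"))
  fp <- fingerprint(coll)

  write_fingerprint_json(fp, file.path("results", paste0("fingerprint_", cond, ".json")))
  write.csv(fp$per_cell, file.path("results", paste0("per_cell_", cond, ".csv")),
            row.names = FALSE)
  write.csv(fp$segments, file.path("results", paste0("segments_", cond, ".csv")),
            row.names = FALSE)

  cat("==", cond, "==\n")
  print(fp)
}

cat("fingerprints, per-cell tables and segment tables are in results/\n")
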
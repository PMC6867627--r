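# shared fixtures, built in code

default_geometry <- function() ring_geometry(0, 0, 75)

# a small deterministic collection for io tests
small_collection <- function(n_cells = 2, n_frames = 10, dt = 1 / 6,
                             seed = 421) {
  set.seed(seed)
  geom <- default_geometry()
  trajs <- lapply(seq_len(n_cells), function(i) {
    phi <- cumsum(c(runif(1, -pi, pi), rnorm(n_frames - 1, 0.03, 0.01)))
    trajectory(sprintf("c%02d", i), (seq_len(n_frames) - 1) * dt, phi,
               geometry = geom)
  })
  trajectory_collection(trajs, geom)
}

# velocity series wrapper for hand-built series
make_vel <- function(v, dt = 1 / 6, cell_id = "cell") {
  structure(list(cell_id = cell_id, times = (seq_along(v) - 1) * dt,
                 v_tang = v, dt = dt,
                 track_start = 0, track_end = (length(v) - 1) * dt),
            class = "velocity_series")
}

# hand-built segment table from labels at frame resolution
make_segments <- function(labels, dt = 1 / 6, cell_id = "cell") {
  seg <- segment_states(make_vel(ifelse(labels == "RUN", 30, 0), dt, cell_id),
                        segmentation_params(v_threshold = 6,
                                            min_state_duration = dt))
  seg
}
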
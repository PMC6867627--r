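#' Parameters of the run/rest classifier
#'
#' The classifier labels a frame RUN when the magnitude of the smoothed
#' tangential velocity reaches `v_threshold`, optionally splits runs at
#' direction reversals, and then absorbs segments shorter than
#' `min_state_duration` into their longer neighbor until all segments meet
#' the minimum. Defaults target the high signal-to-noise regime of
#' micro-lane assays, where run speeds are an order of magnitude above the
#' apparent speed of resting-state wiggling.
#'
#' @param smooth_window Length (h) of the centered moving-average window
#'   applied to the angular position before differentiation in
#'   [tangential_velocity()] (used for the run-velocity measurement).
#' @param v_threshold Minimum |v_tang| (um/h) for an element to count as
#'   RUN.
#' @param min_state_duration Minimum segment duration (h); shorter segments
#'   are merged into a neighbor. The default of 10 minutes equals one frame
#'   at the default imaging cadence, i.e. every resolvable state survives;
#'   larger values progressively concatenate states across short
#'   interruptions and bias the fitted lifetimes upward.
#' @param reversal_breaks_run If `TRUE`, a sign change of the velocity
#'   terminates a RUN segment even without an intervening rest.
#'
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_window = 0.5, v_threshold = 6,
                                min_state_duration = 1 / 6,
                                reversal_breaks_run = TRUE) {
  stopifnot(smooth_window > 0, v_threshold > 0, min_state_duration > 0,
            is.logical(reversal_breaks_run), length(reversal_breaks_run) == 1L)
  structure(list(smooth_window = smooth_window, v_threshold = v_threshold,
                 min_state_duration = min_state_duration,
                 reversal_breaks_run = reversal_breaks_run),
            class = "segmentation_params")
}

# centered moving average with symmetrically shrinking window at the edges
.smooth_centered <- function(x, half) {
  n <- length(x)
  if (half <= 0L || n < 3L) return(x)
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)
  cs <- cumsum(x)
  cs0 <- c(0, cs)
  (cs[i + k] - cs0[i - k]) / (2 * k + 1)
}

#' Tangential velocity along the ring
#'
#' Smooths the angular position with a centered moving average (the window
#' shrinks symmetrically at the track edges) and differentiates it with a
#' central finite difference (one-sided at the endpoints), scaled by the
#' ring radius to give the signed velocity along the lane in um/h.
#'
#' @param traj A [trajectory()].
#' @param geometry [ring_geometry()] supplying the radius.
#' @param smooth_window Moving-average window length in hours.
#'
#' @return Object of class `velocity_series`: list with `cell_id`, `times`,
#'   `v_tang` (um/h), `dt`.
#' @export
tangential_velocity <- function(traj, geometry, smooth_window = 0.5) {
  stopifnot(inherits(traj, "lane_trajectory"), inherits(geometry, "ring_geometry"))
  n <- length(traj$times)
  if (n < 3L) stop("tangential velocity needs at least 3 time points (cell ",
                   traj$cell_id, ")")
  dt <- traj$dt
  half <- floor(max(1L, round(smooth_window / dt)) / 2)
  s <- .smooth_centered(traj$phi, half)
  v <- numeric(n)
  v[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) / (2 * dt)
  v[1L] <- (s[2L] - s[1L]) / dt
  v[n] <- (s[n] - s[n - 1L]) / dt
  structure(list(cell_id = traj$cell_id, times = traj$times,
                 v_tang = geometry$radius * v, dt = dt,
                 track_start = traj$times[1L], track_end = traj$times[n]),
            class = "velocity_series")
}

#' Per-step tangential velocity
#'
#' One-sided velocity of each inter-frame step, evaluated at the midpoint
#' between consecutive frames: `radius * diff(phi) / dt`. Unlike the
#' smoothed central-difference series of [tangential_velocity()], a step
#' velocity never mixes motion from both sides of a frame, so even a
#' single resting step between two runs shows up as a slow element. This
#' is the series the fingerprint pipeline classifies states on; the
#' smoothed series is kept for measuring the run velocity.
#'
#' @param traj A [trajectory()].
#' @param geometry [ring_geometry()].
#'
#' @return A `velocity_series` of length `n - 1` whose `times` are the
#'   step midpoints; `track_start`/`track_end` keep the frame-grid extent
#'   so segments built from it tile the full track.
#' @export
step_velocity <- function(traj, geometry) {
  stopifnot(inherits(traj, "lane_trajectory"), inherits(geometry, "ring_geometry"))
  n <- length(traj$times)
  dt <- traj$dt
  structure(list(cell_id = traj$cell_id,
                 times = traj$times[-n] + dt / 2,
                 v_tang = geometry$radius * diff(traj$phi) / dt,
                 dt = dt,
                 track_start = traj$times[1L], track_end = traj$times[n]),
            class = "velocity_series")
}

#' Segment a velocity series into alternating run and rest states
#'
#' Elements with |v_tang| at or above the threshold are labeled RUN (split
#' at velocity sign changes when `reversal_breaks_run`), all others REST.
#' Segments shorter than the minimum duration are then absorbed
#' iteratively, shortest first, into their longer neighbor (ties absorb
#' into the preceding segment) until every segment meets the minimum or a
#' single segment remains. Each element covers half a sampling interval to
#' either side (clipped to the track extent), so the segments tile the
#' track exactly.
#'
#' The function is agnostic to how the velocity series was obtained: given
#' the smoothed central-difference series of [tangential_velocity()] it
#' labels frames; given the [step_velocity()] series it labels inter-frame
#' steps, which resolves single-step rests that a centered stencil
#' straddles (the fingerprint pipeline uses the latter).
#'
#' @param vel A `velocity_series`.
#' @param params A [segmentation_params()].
#'
#' @return A data frame with columns `cell_id`, `label` ("RUN"/"REST"),
#'   `start`, `end`, `duration` (h), `direction` (+1/-1 for runs, 0 for
#'   rests), `starts_at_track_start`, `ends_at_track_end`. The per-element
#'   labels are attached as attribute `frame_label`.
#' @export
segment_states <- function(vel, params = segmentation_params()) {
  stopifnot(inherits(vel, "velocity_series"), inherits(params, "segmentation_params"))
  v <- vel$v_tang
  t <- vel$times
  dt <- vel$dt
  n <- length(v)
  if (n < 1L) stop("empty velocity series")
  track_start <- if (is.null(vel$track_start)) t[1L] else vel$track_start
  track_end <- if (is.null(vel$track_end)) t[n] else vel$track_end
  edge_first <- min(0, (t[1L] - dt / 2) - track_start)
  edge_last <- min(0, track_end - (t[n] + dt / 2))
  run <- abs(v) >= params$v_threshold
  dirv <- sign(v)
  key <- if (params$reversal_breaks_run) ifelse(run, dirv, 0) else rep(0, n)
  min_dur <- params$min_state_duration
  repeat {
    grp <- cumsum(c(1L, (run[-1L] != run[-n]) | (key[-1L] != key[-n])))
    ng <- grp[n]
    cnt <- tabulate(grp, ng)
    durs <- cnt * dt
    durs[1L] <- durs[1L] + edge_first
    durs[ng] <- durs[ng] + edge_last
    if (ng == 1L) break
    viol <- which(durs < min_dur - 1e-9)
    if (length(viol) == 0L) break
    k <- viol[which.min(durs[viol])]
    nb <- if (k == 1L) 2L
          else if (k == ng) ng - 1L
          else if (durs[k - 1L] >= durs[k + 1L]) k - 1L else k + 1L
    src <- match(nb, grp)          # first frame of the absorbing neighbor
    idx <- which(grp == k)
    run[idx] <- run[src]
    key[idx] <- key[src]
  }
  starts_i <- which(!duplicated(grp))
  ends_i <- c(starts_i[-1L] - 1L, n)
  start_t <- pmax(track_start, t[starts_i] - dt / 2)
  end_t <- pmin(track_end, t[ends_i] + dt / 2)
  ng <- length(starts_i)
  direction <- integer(ng)
  for (j in seq_len(ng)) {
    if (run[starts_i[j]]) {
      direction[j] <- as.integer(sign(mean(v[starts_i[j]:ends_i[j]])))
    }
  }
  seg <- data.frame(
    cell_id = vel$cell_id,
    label = ifelse(run[starts_i], "RUN", "REST"),
    start = start_t,
    end = end_t,
    duration = end_t - start_t,
    direction = direction,
    starts_at_track_start = seq_len(ng) == 1L,
    ends_at_track_end = seq_len(ng) == ng,
    stringsAsFactors = FALSE
  )
  attr(seg, "frame_label") <- ifelse(run, "RUN", "REST")
  seg
}

#' Classify every frame of a trajectory as RUN or REST
#'
#' Convenience wrapper running the state classifier the way the
#' fingerprint pipeline does: states are detected on the per-step velocity
#' ([step_velocity()]), and each frame inherits the label of its outgoing
#' step (the last frame inherits its incoming step).
#'
#' @param traj A [trajectory()].
#' @param geometry [ring_geometry()].
#' @param params [segmentation_params()].
#'
#' @return Character vector of "RUN"/"REST", one element per frame, with
#'   the segment table attached as attribute `segments`.
#' @export
classify_frames <- function(traj, geometry, params = segmentation_params()) {
  seg <- segment_states(step_velocity(traj, geometry), params)
  sl <- attr(seg, "frame_label")
  labels <- c(sl, sl[length(sl)])
  attr(labels, "segments") <- seg
  labels
}
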
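#' Parameters of the two-state trajectory simulator
#'
#' Cells alternate between run states (ballistic angular motion at a
#' per-cell speed, small frame-to-frame jitter) and rest states (random
#' positional wiggling with no net motion). Dwell times in both states are
#' exponential, matching the memoryless single-exponential survival the
#' analysis fits; the per-cell speed is lognormal to reproduce the broad,
#' strictly positive spread of run velocities seen across a population,
#' and a fixed fraction of cells never leaves the rest state.
#'
#' @param tau_run,tau_rest Mean run/rest state lifetimes (h).
#' @param speed_median Median of the per-cell run speed distribution (um/h).
#' @param speed_log_sd Standard deviation of log speed (lognormal spread).
#' @param run_speed_jitter Within-run Gaussian frame noise on the speed
#'   (um/h).
#' @param rest_wiggle_sd Per-frame positional noise during rest (um).
#' @param reversal_prob Probability that a new run reverses direction
#'   relative to the previous run.
#' @param immobile_fraction Fraction of cells simulated as resting for the
#'   whole experiment.
#' @param n_cells Number of cells.
#' @param duration Track duration (h).
#' @param dt Sampling interval (h); must resolve the state lifetimes
#'   (`dt < min(tau_run, tau_rest) / 3`).
#' @param seed Integer seed; all randomness of [simulate_population()]
#'   derives from it through per-cell substreams.
#'
#' @return Object of class `simulation_params`.
#' @export
simulation_params <- function(tau_run = 2, tau_rest = 4, speed_median = 30,
                              speed_log_sd = 0.3, run_speed_jitter = 2,
                              rest_wiggle_sd = 0.3, reversal_prob = 0.5,
                              immobile_fraction = 0.1, n_cells = 300,
                              duration = 48, dt = 1 / 6, seed = 1L) {
  p <- list(tau_run = tau_run, tau_rest = tau_rest,
            speed_median = speed_median, speed_log_sd = speed_log_sd,
            run_speed_jitter = run_speed_jitter,
            rest_wiggle_sd = rest_wiggle_sd, reversal_prob = reversal_prob,
            immobile_fraction = immobile_fraction, n_cells = n_cells,
            duration = duration, dt = dt, seed = as.integer(seed))
  with(p, {
    if (tau_run <= 0 || tau_rest <= 0) stop("state lifetimes must be positive")
    if (speed_median <= 0) stop("speed_median must be positive")
    if (speed_log_sd < 0 || run_speed_jitter < 0 || rest_wiggle_sd < 0) {
      stop("dispersion parameters must be non-negative")
    }
    if (reversal_prob < 0 || reversal_prob > 1 ||
        immobile_fraction < 0 || immobile_fraction > 1) {
      stop("probabilities must lie in [0, 1]")
    }
    if (n_cells < 1L) stop("n_cells must be at least 1")
    if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
    if (dt >= min(tau_run, tau_rest) / 3) {
      stop("dt must be below min(tau_run, tau_rest)/3 to resolve the states")
    }
  })
  structure(p, class = "simulation_params")
}

#' Control-like and induced-like simulation scenarios
#'
#' Convenience parameter sets spanning a motile reference condition and a
#' low-motility condition (slower runs, shorter run states, longer rest
#' states, more fully resting cells). They are plausible test scenarios
#' for directional comparisons, not measurements of any real cell line.
#'
#' @param n_cells Number of cells per condition.
#' @param seed Simulation seed.
#' @param ... Further arguments passed to [simulation_params()].
#' @return A `simulation_params` object.
#' @export
ctrl_like_params <- function(n_cells = 100, seed = 1L, ...) {
  simulation_params(tau_run = 4, tau_rest = 2, speed_median = 30,
                    immobile_fraction = 0.1, n_cells = n_cells, seed = seed,
                    ...)
}

#' @rdname ctrl_like_params
#' @export
induced_like_params <- function(n_cells = 100, seed = 2L, ...) {
  simulation_params(tau_run = 2, tau_rest = 6, speed_median = 20,
                    immobile_fraction = 0.3, n_cells = n_cells, seed = seed,
                    ...)
}

#' Simulate one cell on the ring
#'
#' Draws an alternating run/rest state schedule with exponential dwell
#' times (the initial state is RUN with the stationary probability
#' `tau_run / (tau_run + tau_rest)`, so the renewal process starts in
#' equilibrium), then integrates the angular position frame by frame:
#' during a run the angle advances by `direction * (speed + jitter) * dt /
#' radius`, at each new run the direction flips with `reversal_prob`, and
#' during rest the angle performs a Gaussian wiggle of scale
#' `rest_wiggle_sd / radius` per frame. Uses the current RNG state; seed
#' management lives in [simulate_population()].
#'
#' @param params [simulation_params()].
#' @param cell_speed Run speed of this cell (um/h).
#' @param immobile If `TRUE` the cell rests for the whole track.
#' @param geometry [ring_geometry()].
#' @param cell_id Identifier for the emitted trajectory.
#'
#' @return List with `trajectory` (a [trajectory()]) and `truth`: per-frame
#'   `state` labels, a `segments` data frame of true dwell times (last one
#'   truncated at track end and flagged censored), `cell_speed`, `immobile`.
#' @export
simulate_cell <- function(params, cell_speed, immobile = FALSE,
                          geometry = ring_geometry(), cell_id = "cell") {
  stopifnot(inherits(params, "simulation_params"))
  radius <- geometry$radius
  dt <- params$dt
  nf <- round(params$duration / dt)
  times <- (0:nf) * dt
  n <- nf + 1L

  if (immobile) {
    labs <- "REST"
    durs <- params$duration
    censored <- TRUE
    frame_state <- rep("REST", n)
    dphi <- stats::rnorm(nf, 0, params$rest_wiggle_sd / radius)
  } else {
    p_run0 <- params$tau_run / (params$tau_run + params$tau_rest)
    first_run <- stats::runif(1) < p_run0
    durs <- numeric(0)
    while (sum(durs) <= params$duration + dt) {
      k <- max(8L, ceiling(2 * params$duration /
                             (params$tau_run + params$tau_rest)))
      m <- length(durs)
      is_run <- (seq_len(k) + m) %% 2L == (if (first_run) 1L else 0L)
      tau <- ifelse(is_run, params$tau_run, params$tau_rest)
      durs <- c(durs, stats::rexp(k, 1 / tau))
    }
    ns <- length(durs)
    labs <- if (first_run) rep(c("RUN", "REST"), length.out = ns) else
      rep(c("REST", "RUN"), length.out = ns)
    bounds <- cumsum(durs)
    run_seg <- which(labs == "RUN")
    dir_seg <- integer(ns)
    if (length(run_seg)) {
      first_dir <- sample(c(-1L, 1L), 1L)
      flips <- stats::runif(length(run_seg)) < params$reversal_prob
      flips[1L] <- FALSE
      dir_seg[run_seg] <- first_dir * cumprod(ifelse(flips, -1L, 1L))
    }
    seg_idx <- findInterval(times, bounds) + 1L
    seg_idx[seg_idx > ns] <- ns
    frame_state <- labs[seg_idx]
    frame_dir <- dir_seg[seg_idx]

    st <- frame_state[seq_len(nf)]
    dr <- frame_dir[seq_len(nf)]
    run_f <- st == "RUN"
    dphi <- numeric(nf)
    if (any(run_f)) {
      sp <- cell_speed + stats::rnorm(sum(run_f), 0, params$run_speed_jitter)
      dphi[run_f] <- dr[run_f] * sp * dt / radius
    }
    if (any(!run_f)) {
      dphi[!run_f] <- stats::rnorm(sum(!run_f), 0,
                                   params$rest_wiggle_sd / radius)
    }
    keep <- which(cumsum(c(0, durs)) < params$duration)
    obs_dur <- durs[keep]
    obs_dur[length(keep)] <- params$duration - sum(durs[keep[-length(keep)]])
    labs_k <- labs[keep]
    censored <- c(rep(FALSE, length(keep) - 1L), TRUE)
    durs <- obs_dur
    labs <- labs_k
  }

  phi0 <- stats::runif(1, -pi, pi)
  phi <- phi0 + c(0, cumsum(dphi))
  traj <- trajectory(cell_id, times, phi, geometry = geometry,
                     validate = FALSE)
  list(trajectory = traj,
       truth = list(state = frame_state,
                    segments = data.frame(cell_id = cell_id, label = labs,
                                          duration = durs,
                                          censored = censored,
                                          stringsAsFactors = FALSE),
                    cell_speed = if (immobile) NA_real_ else cell_speed,
                    immobile = immobile))
}

#' Simulate a population of cells on ring micro-lanes
#'
#' Draws per-cell run speeds from a lognormal with the configured median
#' and log-sd, marks a fraction of cells immobile, and simulates each cell
#' with its own reproducible substream derived from `params$seed`, so the
#' same parameters always yield bitwise-identical output regardless of
#' evaluation order.
#'
#' @param params [simulation_params()].
#' @param geometry [ring_geometry()].
#'
#' @return Object of class `lane_simulation`: list with `collection` (a
#'   [trajectory_collection()]), and `truth` containing `cells` (per-cell
#'   speed and immobile flag), `segments` (true dwell times of all cells)
#'   and `frame_states` (cells x frames character matrix of true labels).
#' @export
simulate_population <- function(params, geometry = ring_geometry()) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(params$seed)
  n <- params$n_cells
  immobile <- stats::runif(n) < params$immobile_fraction
  speeds <- stats::rlnorm(n, log(params$speed_median), params$speed_log_sd)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("cell_%04d", seq_len(n))

  trajs <- vector("list", n)
  seg_parts <- vector("list", n)
  nf <- round(params$duration / params$dt) + 1L
  frame_states <- matrix(NA_character_, nrow = n, ncol = nf,
                         dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    set.seed(cell_seeds[i])
    sim <- simulate_cell(params, speeds[i], immobile = immobile[i],
                         geometry = geometry, cell_id = ids[i])
    trajs[[i]] <- sim$trajectory
    seg_parts[[i]] <- sim$truth$segments
    frame_states[i, ] <- sim$truth$state
  }
  segments <- do.call(rbind, seg_parts)
  rownames(segments) <- NULL
  cells <- data.frame(cell_id = ids, cell_speed = ifelse(immobile, NA, speeds),
                      immobile = immobile, stringsAsFactors = FALSE)
  structure(list(collection = trajectory_collection(trajs, geometry),
                 truth = list(cells = cells, segments = segments,
                              frame_states = frame_states),
                 params = params),
            class = "lane_simulation")
}

#' @export
print.lane_simulation <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("two-state lane simulation: %d cells x %g h (dt %.3g h), ",
                     "tau_run %g h, tau_rest %g h, median speed %g um/h, ",
                     "immobile %g, seed %d\n"),
              p$n_cells, p$duration, p$dt, p$tau_run, p$tau_rest,
              p$speed_median, p$immobile_fraction, p$seed))
  invisible(x)
}

#' Write simulated data to disk
#'
#' Emits the trajectory CSV (via [write_trajectories()]), a ground-truth
#' CSV (`cell_id`, `frame`, `time_h`, `true_state`, `cell_speed`,
#' `immobile`) and a JSON manifest of the simulation parameters, so a run
#' can be reproduced exactly from its manifest.
#'
#' @param sim A `lane_simulation` from [simulate_population()].
#' @param tracks_path,truth_path,manifest_path Output file paths; `NULL`
#'   skips that file.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, tracks_path, truth_path = NULL,
                             manifest_path = NULL) {
  stopifnot(inherits(sim, "lane_simulation"))
  write_trajectories(sim$collection, tracks_path)
  written <- tracks_path
  if (!is.null(truth_path)) {
    fs <- sim$truth$frame_states
    n <- nrow(fs); nf <- ncol(fs)
    truth <- data.frame(
      cell_id = rep(rownames(fs), each = nf),
      frame = rep(seq_len(nf) - 1L, times = n),
      time_h = rep((seq_len(nf) - 1L) * sim$params$dt, times = n),
      true_state = as.vector(t(fs)),
      cell_speed = rep(sim$truth$cells$cell_speed, each = nf),
      immobile = rep(sim$truth$cells$immobile, each = nf),
      stringsAsFactors = FALSE)
    utils::write.csv(truth, truth_path, row.names = FALSE)
    written <- c(written, truth_path)
  }
  if (!is.null(manifest_path)) {
    jsonlite::write_json(unclass(sim$params), manifest_path,
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    written <- c(written, manifest_path)
  }
  invisible(written)
}

#' Re-create simulation parameters from a manifest
#'
#' @param manifest_path JSON manifest written by [write_simulation()].
#' @return A [simulation_params()] object.
#' @export
read_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  simulation_params(tau_run = m$tau_run, tau_rest = m$tau_rest,
                    speed_median = m$speed_median,
                    speed_log_sd = m$speed_log_sd,
                    run_speed_jitter = m$run_speed_jitter,
                    rest_wiggle_sd = m$rest_wiggle_sd,
                    reversal_prob = m$reversal_prob,
                    immobile_fraction = m$immobile_fraction,
                    n_cells = m$n_cells, duration = m$duration, dt = m$dt,
                    seed = m$seed)
}
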
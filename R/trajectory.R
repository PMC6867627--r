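#' Single-cell trajectory on a ring micro-lane
#'
#' A trajectory is one cell's uniformly sampled time series of unwrapped
#' angular position. Times are in hours, angles in radians; if a geometry
#' is supplied the arc-length position `arc = radius * phi` (um) is stored
#' alongside.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param times Numeric vector of observation times (hours), strictly
#'   increasing and uniformly spaced (relative tolerance 1e-6 on the step).
#' @param phi Numeric vector of unwrapped angular positions (radians), same
#'   length as `times`; successive steps must have magnitude below pi.
#' @param geometry Optional [ring_geometry()]; if given, `arc` is computed.
#' @param validate Set to `FALSE` to skip invariant checks (internal use on
#'   already-validated data).
#'
#' @return An object of class `lane_trajectory`: list with `cell_id`,
#'   `times`, `phi`, `dt` (sampling interval, h) and optionally `arc`.
#' @export
trajectory <- function(cell_id, times, phi, geometry = NULL, validate = TRUE) {
  times <- as.numeric(times)
  phi <- as.numeric(phi)
  if (validate) {
    if (length(times) != length(phi)) {
      stop("times and phi must have equal length for cell ", cell_id)
    }
    if (length(times) < 2L) {
      stop("trajectory of cell ", cell_id, " needs at least 2 time points")
    }
    d <- diff(times)
    if (any(d <= 0)) stop("times must be strictly increasing for cell ", cell_id)
    dt <- times[2L] - times[1L]
    if (max(abs(d - dt)) > 1e-6 * dt) {
      stop("non-uniform sampling for cell ", cell_id,
           " (max deviation ", signif(max(abs(d - dt)), 3), " h)")
    }
    dphi <- abs(diff(phi))
    if (any(dphi >= pi)) {
      stop("angular step of magnitude >= pi in cell ", cell_id,
           ": unwrapping failed or sampling too slow")
    }
  } else {
    dt <- times[2L] - times[1L]
  }
  out <- list(cell_id = as.character(cell_id), times = times, phi = phi,
              dt = dt)
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "ring_geometry"))
    out$arc <- geometry$radius * phi
  }
  structure(out, class = "lane_trajectory")
}

#' @export
print.lane_trajectory <- function(x, ...) {
  cat(sprintf("trajectory of cell %s: %d frames, dt = %.4g h, span %.4g h\n",
              x$cell_id, length(x$times), x$dt,
              x$times[length(x$times)] - x$times[1L]))
  invisible(x)
}

#' Collection of trajectories sharing one ring geometry
#'
#' @param trajectories List of [trajectory()] objects with unique cell ids
#'   and a common sampling interval.
#' @param geometry Shared [ring_geometry()].
#'
#' @return Object of class `trajectory_collection`: list with
#'   `trajectories` (named by cell id), `geometry`, `dt`.
#' @export
trajectory_collection <- function(trajectories, geometry) {
  stopifnot(inherits(geometry, "ring_geometry"), length(trajectories) >= 1L)
  ok <- vapply(trajectories, inherits, logical(1), "lane_trajectory")
  if (!all(ok)) stop("all elements must be lane_trajectory objects")
  ids <- vapply(trajectories, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) {
    stop("duplicate cell ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dts <- vapply(trajectories, `[[`, numeric(1), "dt")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    stop("trajectories do not share a common sampling interval")
  }
  names(trajectories) <- ids
  structure(list(trajectories = trajectories, geometry = geometry, dt = dt),
            class = "trajectory_collection")
}

#' @export
length.trajectory_collection <- function(x) length(x$trajectories)

#' @export
print.trajectory_collection <- function(x, ...) {
  cat(sprintf("trajectory collection: %d cells, dt = %.4g h, ring radius %g um\n",
              length(x$trajectories), x$dt, x$geometry$radius))
  invisible(x)
}

#' Default column mapping for trajectory tables
#'
#' @param cell_id,time,x,y,phi Column names in the CSV holding the cell
#'   identifier, time stamp, Cartesian coordinates (um) and/or angular
#'   position (radians). Either both `x` and `y` or `phi` must be present
#'   in the file.
#' @return Named list used as the `dialect` argument of
#'   [read_trajectories()].
#' @export
trajectory_dialect <- function(cell_id = "cell_id", time = "time_h",
                               x = "x_um", y = "y_um", phi = "phi_rad") {
  list(cell_id = cell_id, time = time, x = x, y = y, phi = phi)
}

#' Read a trajectory table from CSV
#'
#' Reads a tracking table with one row per cell and frame, sorts rows per
#' cell by time, converts times to hours, projects Cartesian coordinates
#' onto the ring (if no angle column is present) and unwraps angles into
#' continuous angular positions. Cells with fewer than two rows are dropped
#' with a warning. Cells whose mean absolute radial deviation exceeds 20%
#' of the lane radius are flagged (attribute `flagged_cells`), not dropped.
#'
#' @param path CSV file path.
#' @param geometry [ring_geometry()] of the lane array.
#' @param dialect Column mapping, see [trajectory_dialect()].
#' @param time_unit One of `"hours"`, `"minutes"`, `"frames"`; frame counts
#'   are converted with `frame_interval`.
#' @param frame_interval Sampling interval in hours, required when
#'   `time_unit = "frames"`.
#'
#' @return A [trajectory_collection()]. Attribute `flagged_cells` lists the
#'   ids of cells straying off the lane.
#' @export
read_trajectories <- function(path, geometry = ring_geometry(),
                              dialect = trajectory_dialect(),
                              time_unit = c("hours", "minutes", "frames"),
                              frame_interval = NULL) {
  time_unit <- match.arg(time_unit)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty trajectory file: ", path)
  need <- c(dialect$cell_id, dialect$time)
  have_phi <- dialect$phi %in% names(tab)
  have_xy <- all(c(dialect$x, dialect$y) %in% names(tab))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) || !(have_phi || have_xy)) {
    stop("trajectory file ", path, " lacks required columns: need ",
         paste(need, collapse = ", "), " plus either (",
         dialect$x, ", ", dialect$y, ") or ", dialect$phi)
  }
  tt <- as.numeric(tab[[dialect$time]])
  tt <- switch(time_unit,
               hours = tt,
               minutes = tt / 60,
               frames = {
                 if (is.null(frame_interval)) {
                   stop("frame_interval (hours) required when time_unit = 'frames'")
                 }
                 tt * frame_interval
               })
  ids <- as.character(tab[[dialect$cell_id]])
  flagged <- character(0)
  trajs <- list()
  for (id in unique(ids)) {
    rows <- which(ids == id)
    if (length(rows) < 2L) {
      warning("cell ", id, " has fewer than 2 time points and was dropped")
      next
    }
    ord <- rows[order(tt[rows])]
    if (have_phi) {
      raw <- as.numeric(tab[[dialect$phi]][ord])
      rdev <- NULL
    } else {
      pr <- project_to_ring(as.numeric(tab[[dialect$x]][ord]),
                            as.numeric(tab[[dialect$y]][ord]), geometry)
      raw <- pr$theta
      rdev <- pr$radial_dev
    }
    phi <- unwrap_angles(raw)
    if (!is.null(rdev) && mean(abs(rdev)) > 0.2 * geometry$radius) {
      flagged <- c(flagged, id)
    }
    trajs[[id]] <- trajectory(id, tt[ord], phi, geometry = geometry)
  }
  if (length(trajs) == 0L) stop("no usable trajectories in ", path)
  if (length(flagged)) {
    warning(length(flagged), " cell(s) stray more than 20% of the radius ",
            "off the lane: ", paste(flagged, collapse = ", "))
  }
  coll <- trajectory_collection(trajs, geometry)
  attr(coll, "flagged_cells") <- flagged
  coll
}

#' Write a trajectory collection to a normalized CSV
#'
#' Columns: `cell_id`, `time_h`, `phi_rad`, `arc_um`.
#'
#' @param collection A [trajectory_collection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(collection, path) {
  stopifnot(inherits(collection, "trajectory_collection"))
  r <- collection$geometry$radius
  parts <- lapply(collection$trajectories, function(tr) {
    data.frame(cell_id = tr$cell_id, time_h = tr$times, phi_rad = tr$phi,
               arc_um = r * tr$phi, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
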
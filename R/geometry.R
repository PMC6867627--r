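#' Ring micro-lane geometry
#'
#' Describes a circular micro-lane by its center and radius. Cells confined
#' to such a lane move effectively in one dimension; their position is the
#' (unwrapped) angle on the ring, and arc length is `radius * phi`.
#'
#' @param center_x,center_y Center of the ring in micrometers.
#' @param radius Ring radius in micrometers; must be positive. The default
#'   corresponds to a 150 um ring diameter, a typical micro-lane size for
#'   single epithelial/mesenchymal cells.
#'
#' @return An object of class `ring_geometry`: a list with elements
#'   `center_x`, `center_y`, `radius`.
#' @examples
#' geom <- ring_geometry(radius = 75)
#' @export
ring_geometry <- function(center_x = 0, center_y = 0, radius = 75) {
  stopifnot(is.numeric(center_x), length(center_x) == 1L, is.finite(center_x),
            is.numeric(center_y), length(center_y) == 1L, is.finite(center_y),
            is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("ring radius must be positive")
  structure(list(center_x = as.numeric(center_x),
                 center_y = as.numeric(center_y),
                 radius = as.numeric(radius)),
            class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("ring geometry: center (%g, %g) um, radius %g um\n",
              x$center_x, x$center_y, x$radius))
  invisible(x)
}

#' Project Cartesian tracking coordinates onto a ring
#'
#' Maps (x, y) positions to the polar angle around the ring center, using
#' the `atan2` convention (radians in (-pi, pi], positive counter-clockwise).
#' The radial deviation from the nominal lane radius is returned per point
#' as a quality-control quantity: cells that leave the adhesive lane show
#' large deviations.
#'
#' @param x,y Numeric vectors of positions in micrometers.
#' @param geometry A [ring_geometry()].
#'
#' @return A list with components `theta` (raw angle per point, radians)
#'   and `radial_dev` (distance from center minus the lane radius, um).
#' @examples
#' project_to_ring(c(75, 0), c(0, 75), ring_geometry())$theta
#' @export
project_to_ring <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "ring_geometry"), length(x) == length(y))
  dx <- x - geometry$center_x
  dy <- y - geometry$center_y
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0)) {
    stop("point(s) coincident with the ring center cannot be projected (index ",
         which(r == 0)[1L], ")")
  }
  list(theta = atan2(dy, dx), radial_dev = r - geometry$radius)
}

#' Unwrap a sequence of raw angles into a continuous angular position
#'
#' Removes 2*pi jumps from a wrapped angle series so that successive steps
#' have magnitude below pi, yielding the continuous angular position a cell
#' traces out on the ring (laps accumulate instead of wrapping).
#'
#' @param raw Numeric vector of raw angles (radians), e.g. from
#'   [project_to_ring()].
#' @param tol Absolute tolerance used to flag a step of magnitude exactly
#'   `pi`, which is directionally ambiguous and raises an error.
#'
#' @return Numeric vector `phi` with `phi[1] == raw[1]` and every step the
#'   minimal-magnitude representative of the raw step modulo 2*pi.
#' @examples
#' unwrap_angles(c(3.0, -3.0))   # crosses -pi: c(3.0, 3.0 + (2*pi - 6))
#' @export
unwrap_angles <- function(raw, tol = 1e-12) {
  stopifnot(is.numeric(raw))
  n <- length(raw)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(as.numeric(raw))
  d <- diff(raw)
  adj <- d - 2 * pi * round(d / (2 * pi))
  amb <- abs(abs(adj) - pi) < tol
  if (any(amb)) {
    stop("ambiguous angular step of magnitude pi at index ", which(amb)[1L],
         ": direction of travel cannot be determined")
  }
  raw[1L] + cumsum(c(0, adj))
}

#' Wrap angles into (-pi, pi]
#'
#' Inverse companion of [unwrap_angles()], mainly useful for simulating
#' raw detector output and in round-trip tests.
#'
#' @param phi Numeric vector of angles (radians).
#' @return Angles mapped into (-pi, pi].
#' @export
wrap_angles <- function(phi) {
  w <- phi - 2 * pi * round(phi / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}
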
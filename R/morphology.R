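#' Binary cell (or nucleus) mask
#'
#' @param m Logical or 0/1 numeric matrix; `TRUE`/nonzero marks foreground.
#' @param pixel_size Edge length of one pixel in micrometers.
#'
#' @return Object of class `cell_mask`.
#' @export
cell_mask <- function(m, pixel_size = 1) {
  if (is.numeric(m)) m <- m > 0
  stopifnot(is.matrix(m), is.logical(m), pixel_size > 0)
  if (!any(m)) stop("empty mask: no foreground pixels")
  structure(list(mask = m, pixel_size = pixel_size), class = "cell_mask")
}

#' Shape factor from minimum and maximum Feret diameter
#'
#' The widest spread of the object is the maximum Feret diameter (largest
#' distance between two boundary points); the narrowest spread is the
#' minimum Feret diameter (smallest projection width over all orientations,
#' evaluated on a 1-degree grid). Their ratio is 1 for a disc and
#' approaches 0 for a needle, so a drop in the shape factor reads as a
#' more elongated, spindle-like cell.
#'
#' @param mask A [cell_mask()] (or a matrix, converted with pixel size 1).
#' @param angle_step Orientation grid spacing in degrees for the minimum
#'   Feret search.
#'
#' @return List with `max_spread` (um), `min_spread` (um) and
#'   `shape_factor = min_spread / max_spread`.
#' @export
shape_factor <- function(mask, angle_step = 1) {
  if (!inherits(mask, "cell_mask")) mask <- cell_mask(mask)
  m <- mask$mask
  ncomp <- max(EBImage::bwlabel(m * 1))
  if (ncomp > 1L) {
    stop("mask has ", ncomp, " connected components; label and split first")
  }
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind(idx[, 1L], idx[, 2L]) * mask$pixel_size
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  d2max <- 0
  nh <- nrow(hp)
  for (i in seq_len(nh)) {
    dx <- hp[, 1L] - hp[i, 1L]
    dy <- hp[, 2L] - hp[i, 2L]
    d2max <- max(d2max, max(dx^2 + dy^2))
  }
  # extents are measured between pixel centers, which undershoot the true
  # object boundary by 0 to 1 px depending on how the lattice meets the
  # edge; half a pixel is added as the balanced correction
  max_spread <- sqrt(d2max) + 0.5 * mask$pixel_size
  ang <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  widths <- vapply(ang, function(a) {
    proj <- hp[, 1L] * cos(a) + hp[, 2L] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  min_spread <- min(widths) + 0.5 * mask$pixel_size
  list(max_spread = max_spread, min_spread = min_spread,
       shape_factor = min_spread / max_spread)
}

#' Total staining intensity relative to a reference
#'
#' Sums the image intensity over the mask foreground and divides by a
#' reference value (typically the mean total intensity of the control
#' condition), so the control normalizes to 1.
#'
#' @param image Numeric intensity matrix, same dimensions as the mask.
#' @param mask A [cell_mask()] (or matrix).
#' @param reference Positive scalar to normalize by.
#'
#' @return Dimensionless relative intensity.
#' @export
relative_intensity <- function(image, mask, reference) {
  if (!inherits(mask, "cell_mask")) mask <- cell_mask(mask)
  stopifnot(is.matrix(image), reference > 0)
  if (!all(dim(image) == dim(mask$mask))) {
    stop("image and mask dimensions differ")
  }
  sum(image[mask$mask]) / reference
}

# ---- synthetic mask generators (test fixtures, built in code) -------------

#' Synthetic binary masks
#'
#' Parametric generators for the shapes used to validate the morphology
#' metrics: discs, rotated ellipses and rectangles, and a lens-shaped
#' "spindle" (intersection of two discs). All return a [cell_mask()].
#'
#' @param radius Disc radius in pixels.
#' @param a,b Ellipse semi-axes (pixels).
#' @param width,height Rectangle extents (pixels).
#' @param theta Rotation angle (radians).
#' @param length,thickness Spindle tip-to-tip length and central thickness
#'   (pixels).
#' @param margin Background margin around the shape (pixels).
#' @param pixel_size Pixel size in micrometers.
#' @return A [cell_mask()].
#' @name synthetic_masks
NULL

.shape_grid <- function(half_extent, margin) {
  n <- 2L * ceiling(half_extent + margin) + 1L
  c0 <- (n + 1) / 2
  list(n = n, x = matrix(rep(seq_len(n) - c0, times = n), nrow = n),
       y = matrix(rep(seq_len(n) - c0, each = n), nrow = n))
}

#' @rdname synthetic_masks
#' @export
make_disc_mask <- function(radius, margin = 5, pixel_size = 1) {
  make_ellipse_mask(radius, radius, theta = 0, margin = margin,
                    pixel_size = pixel_size)
}

#' @rdname synthetic_masks
#' @export
make_ellipse_mask <- function(a, b, theta = 0, margin = 5, pixel_size = 1) {
  g <- .shape_grid(max(a, b), margin)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  cell_mask((xr / a)^2 + (yr / b)^2 <= 1, pixel_size)
}

#' @rdname synthetic_masks
#' @export
make_rect_mask <- function(width, height, theta = 0, margin = 5,
                           pixel_size = 1) {
  g <- .shape_grid(sqrt(width^2 + height^2) / 2, margin)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  cell_mask(abs(xr) <= width / 2 & abs(yr) <= height / 2, pixel_size)
}

#' @rdname synthetic_masks
#' @export
make_spindle_mask <- function(length, thickness, theta = 0, margin = 5,
                              pixel_size = 1) {
  stopifnot(thickness < length)
  half_len <- length / 2
  half_th <- thickness / 2
  # lens = intersection of two discs of radius R centered at (0, +-c)
  R <- (half_len^2 + half_th^2) / (2 * half_th)
  cc <- R - half_th
  g <- .shape_grid(half_len, margin)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  cell_mask(xr^2 + (yr - cc)^2 <= R^2 & xr^2 + (yr + cc)^2 <= R^2,
            pixel_size)
}

#' Read a binary mask from a PNG or TIFF file
#'
#' Multi-channel images are reduced to their first channel; pixels above
#' 0.5 (on the 0-1 scale) are foreground.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @param pixel_size Pixel size in micrometers.
#' @return A [cell_mask()].
#' @export
read_mask <- function(path, pixel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG masks requires the 'png' package")
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF masks requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported mask format: .", ext)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  cell_mask(img > 0.5, pixel_size)
}
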
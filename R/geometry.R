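#' Detector geometry for a small-angle/wide-angle diffraction setup
#'
#' Describes the measurement geometry of a 2D photon-counting detector:
#' X-ray wavelength, sample-to-detector distance, pixel pitch, detector grid
#' size and the beam-center position. The geometry governs the conversion
#' between a real-space period \eqn{d}, the transfer momentum
#' \eqn{q = 4\pi \sin\theta / \lambda = 2\pi/d}, and the radius (in pixels)
#' at which the corresponding diffraction feature appears on the detector.
#'
#' The defaults describe a compact Cu-anode instrument: \eqn{\lambda} =
#' 0.1540562 nm (8.04 keV), a 256 x 256 grid of 55 um pixels, and a
#' sample-to-detector distance chosen so the recorded window spans roughly
#' 2 to 13 nm^-1, which places the keratin arcs at d = 0.98 nm and
#' d = 0.51 nm strictly inside the detector.
#'
#' Conventions: pixel indices are 0-based; the beam center is stored as
#' fractional \code{c(row, col)}; radii are float pixels; angles are degrees,
#' 0 along the +x (column) axis, increasing counter-clockwise in (col, row).
#'
#' @param wavelength_nm X-ray wavelength in nm.
#' @param distance_mm Sample-to-detector distance in mm.
#' @param pixel_um Detector pixel pitch in microns (square pixels).
#' @param shape Integer detector grid size, \code{c(rows, cols)}.
#' @param center_px Beam center as fractional 0-based \code{c(row, col)};
#'   default is the geometric center of the grid.
#' @return An object of class \code{"detector_geometry"}.
#' @examples
#' geom <- detector_geometry()
#' d_to_radius(0.98, geom)
#' radius_to_q(60, geom)
#' @export
detector_geometry <- function(wavelength_nm = 0.1540562,
                              distance_mm = 21,
                              pixel_um = 55,
                              shape = c(256L, 256L),
                              center_px = (shape - 1) / 2) {
  stopifnot(wavelength_nm > 0, distance_mm > 0, pixel_um > 0,
            length(shape) == 2, all(shape >= 8),
            length(center_px) == 2)
  geom <- structure(
    list(wavelength_nm = wavelength_nm,
         distance_mm = distance_mm,
         pixel_um = pixel_um,
         shape = as.integer(shape),
         center_px = as.numeric(center_px)),
    class = "detector_geometry")
  # the two keratin periods must land on the detector for this geometry
  for (d in c(0.51, 0.98)) {
    r <- d_to_radius(d, geom)
    if (!is.finite(r) || r >= min(geom$shape) / 2)
      stop(sprintf("geometry places the d = %.2f nm arc off-detector (r = %.1f px)",
                   d, r))
  }
  geom
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> lambda = %.7f nm, D = %g mm, pixel = %g um, %d x %d, center (%.2f, %.2f)\n",
    x$wavelength_nm, x$distance_mm, x$pixel_um, x$shape[1], x$shape[2],
    x$center_px[1], x$center_px[2]))
  qmax <- radius_to_q(min(x$shape) / 2, x)
  cat(sprintf("  recorded q window: up to ~%.1f nm^-1 at the inscribed-disk edge\n", qmax))
  invisible(x)
}

#' Convert a lattice period to transfer momentum
#'
#' \eqn{q = 2\pi/d}, in nm^-1 for \code{d_nm} in nm. Geometry-independent.
#' @param d_nm Real-space period in nm.
#' @return Transfer momentum in nm^-1.
#' @export
d_to_q <- function(d_nm) {
  stopifnot(all(d_nm > 0))
  2 * pi / d_nm
}

#' Convert a lattice period to a detector radius
#'
#' Uses the Bragg condition \eqn{\sin\theta = \lambda/(2d)} and the flat
#' detector projection \eqn{r = (D/p)\tan 2\theta} with \eqn{D} the
#' sample-to-detector distance and \eqn{p} the pixel pitch.
#'
#' @param d_nm Real-space period in nm; requires \eqn{2d > \lambda}.
#' @param geom A \code{\link{detector_geometry}}.
#' @return Radius in pixels from the beam center.
#' @export
d_to_radius <- function(d_nm, geom) {
  stopifnot(inherits(geom, "detector_geometry"), all(d_nm > 0))
  s <- geom$wavelength_nm / (2 * d_nm)
  if (any(s >= 1))
    stop(sprintf("Bragg condition unsolvable: 2d <= lambda for d = %g nm", d_nm[s >= 1][1]))
  theta <- asin(s)
  (geom$distance_mm * 1000 / geom$pixel_um) * tan(2 * theta)
}

#' Convert transfer momentum to a detector radius
#' @param q_nm Transfer momentum in nm^-1.
#' @inheritParams d_to_radius
#' @return Radius in pixels.
#' @export
q_to_radius <- function(q_nm, geom) {
  d_to_radius(2 * pi / q_nm, geom)
}

#' Convert a detector radius to transfer momentum
#' @param r_px Radius in pixels from the beam center.
#' @inheritParams d_to_radius
#' @return Transfer momentum in nm^-1.
#' @export
radius_to_q <- function(r_px, geom) {
  stopifnot(inherits(geom, "detector_geometry"), all(r_px >= 0))
  two_theta <- atan(r_px * geom$pixel_um / (geom$distance_mm * 1000))
  4 * pi * sin(two_theta / 2) / geom$wavelength_nm
}

# dx, dy, r, theta (deg, in [0, 360)) for every pixel relative to a center.
# Rows index y, columns x; 0-based pixel coordinates. A small keyed cache
# avoids recomputing the grid for recurring centers (notably the geometric
# detector center used by rendering, resampling and profile extraction).
.grid_cache <- new.env(parent = emptyenv())
pixel_grid <- function(shape, center_px) {
  key <- paste(c(shape, round(center_px, 6)), collapse = ",")
  hit <- .grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  dy <- matrix(seq_len(shape[1]) - 1 - center_px[1], shape[1], shape[2])
  dx <- matrix(seq_len(shape[2]) - 1 - center_px[2], shape[1], shape[2],
               byrow = TRUE)
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  g <- list(dx = dx, dy = dy, r = r, theta = theta)
  if (length(ls(.grid_cache)) < 8) assign(key, g, .grid_cache)
  g
}
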
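# run code under a local RNG state so package functions never disturb the
# caller's stream; seed must be a single integer
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

new_raw_image <- function(counts, sample_id = NA_character_,
                          patient_id = NA_character_,
                          batch_id = NA_character_,
                          label = "unknown") {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(counts == round(counts)))
  structure(list(counts = counts, sample_id = sample_id,
                 patient_id = patient_id, batch_id = batch_id,
                 label = label),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %d x %d, total %.3g counts, sample %s patient %s label %s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              x$sample_id, x$patient_id, x$label))
  invisible(x)
}

# normalized two-lobed angular profile: mean over theta is 1, so the
# oriented and isotropic arc components mix on a common intensity scale
angular_lobes <- function(theta_deg, orientation_deg, conc) {
  if (conc == 0) return(rep(1, length(theta_deg)))
  x <- 2 * (theta_deg - orientation_deg) * pi / 180
  m <- exp(conc * (cos(x) - 1))
  # mean of exp(conc*(cos-1)) over a period is exp(-conc) I0(conc)
  m / (exp(-conc) * besselI(conc, 0, expon.scaled = FALSE))
}

#' Expected (noise-free) intensity surface of a synthetic claw pattern
#'
#' Closed-form expectation of \code{\link{render_pattern}} before Poisson
#' noise and pixel defects: amorphous background, primary-beam spot and, for
#' each keratin arc, a radial Gaussian times a two-lobed angular profile
#' centered on \code{orientation_deg} and its antipode, mixed with an
#' isotropic ring according to \code{ring_fraction}. The surface is scaled so
#' its integral equals \code{total_counts}.
#'
#' @param structure A \code{\link{structure_model}}.
#' @param geom A \code{\link{detector_geometry}}.
#' @param orientation_deg Fiber orientation of the pattern, degrees.
#' @param total_counts Target integral of the expected surface.
#' @return Numeric matrix of expected counts, dimension \code{geom$shape}.
#' @export
pattern_expectation <- function(structure, geom, orientation_deg = 0,
                                total_counts = 5e6) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(geom, "detector_geometry"), total_counts > 0)
  g <- pixel_grid(geom$shape, geom$center_px)
  e <- structure$background_level * exp(-g$r / structure$background_scale) +
    structure$beam_amplitude * exp(-g$r^2 / (2 * structure$beam_sigma^2))
  for (i in seq_along(structure$arc_d_nm)) {
    r0 <- d_to_radius(structure$arc_d_nm[i], geom)
    radial <- exp(-(g$r - r0)^2 / (2 * structure$arc_radial_sigma[i]^2))
    f <- structure$ring_fraction[i]
    ang <- (1 - f) *
      angular_lobes(g$theta, orientation_deg, structure$arc_angular_conc[i]) + f
    e <- e + structure$arc_amplitude[i] * radial * ang
  }
  s <- sum(e)
  if (s == 0) return(e)  # fully empty structure: nothing to scale
  e * (total_counts / s)
}

#' Render one synthetic claw-XRD detector frame
#'
#' Draws Poisson counts around \code{\link{pattern_expectation}}, then forces
#' dead pixels to zero and injects saturating hot pixels at uniformly random
#' positions (defects are applied after the counting noise, as on a real
#' detector readout). If \code{total_counts} is \code{NULL} the raw integral
#' is drawn uniformly from \code{structure$total_counts_range}. Reproducible:
#' identical arguments and \code{seed} give identical count grids.
#'
#' @inheritParams pattern_expectation
#' @param seed Integer seed for the frame's noise and defects.
#' @param total_counts Target raw integral; \code{NULL} to draw from the
#'   model's range.
#' @param sample_id,patient_id,batch_id,label Identity carried on the frame.
#' @return A \code{raw_image}: integer count matrix plus identity fields.
#' @export
render_pattern <- function(structure, geom, orientation_deg = 0, seed = 1,
                           total_counts = NULL,
                           sample_id = NA_character_,
                           patient_id = NA_character_,
                           batch_id = NA_character_,
                           label = "unknown") {
  with_local_seed(seed, {
    if (is.null(total_counts))
      total_counts <- stats::runif(1, structure$total_counts_range[1],
                                   structure$total_counts_range[2])
    e <- pattern_expectation(structure, geom, orientation_deg, total_counts)
    counts <- matrix(stats::rpois(length(e), e), nrow(e), ncol(e))
    npx <- length(counts)
    n_dead <- stats::rbinom(1, npx, structure$dead_pixel_rate)
    if (n_dead > 0) counts[sample.int(npx, n_dead)] <- 0L
    n_hot <- stats::rbinom(1, npx, structure$hot_pixel_rate)
    hot_idx <- if (n_hot > 0) sample.int(npx, n_hot) else integer(0)
    if (n_hot > 0) counts[hot_idx] <- structure$hot_value
    img <- new_raw_image(counts, sample_id, patient_id, batch_id, label)
    img$hot_idx <- hot_idx  # simulator ground truth, for repair validation
    img$orientation_deg <- orientation_deg %% 180
    img
  })
}

#' Render a silver behenate (AgBH) calibration frame
#'
#' Concentric rings at the AgBH lamellar period d(001) = 5.838 nm and its
#' harmonics d(001)/k, for every harmonic whose radius falls on the detector.
#' Ring amplitudes decay with harmonic order; a beam spot and a weak
#' background are included. Used to measure the q-scale of a batch.
#'
#' @inheritParams render_pattern
#' @param d001_nm AgBH lamellar period, nm.
#' @param total_counts Target raw integral of the frame.
#' @return A \code{raw_image} with attribute fields \code{ring_radii_px} and
#'   \code{ring_harmonics} (simulator ground truth).
#' @export
render_agbh <- function(geom, seed = 1, d001_nm = 5.838, total_counts = 4e6,
                        batch_id = NA_character_) {
  stopifnot(inherits(geom, "detector_geometry"))
  radii <- agbh_ring_radii(geom, d001_nm)
  g <- pixel_grid(geom$shape, geom$center_px)
  e <- 0.15 * exp(-g$r / 80) + 300 * exp(-g$r^2 / (2 * 4^2))
  for (i in seq_along(radii$r_px))
    e <- e + radii$harmonic[i]^-1.5 *
      exp(-(g$r - radii$r_px[i])^2 / (2 * 1.5^2))
  e <- e * (total_counts / sum(e))
  with_local_seed(seed, {
    counts <- matrix(stats::rpois(length(e), e), nrow(e), ncol(e))
    img <- new_raw_image(counts, sample_id = "agbh", batch_id = batch_id)
    img$ring_radii_px <- radii$r_px
    img$ring_harmonics <- radii$harmonic
    img
  })
}

#' AgBH harmonic ring positions for a geometry
#'
#' Radii (pixels) and orders of the AgBH harmonics d(001)/k that fall inside
#' the detector's inscribed disk. The fundamental at q = 2\eqn{\pi}/5.838
#' ~ 1.08 nm^-1 sits below a 2 nm^-1 recording window, so the first ring
#' used for calibration is a harmonic.
#'
#' @inheritParams render_agbh
#' @return \code{data.frame(harmonic, d_nm, q_nm, r_px)}.
#' @export
agbh_ring_radii <- function(geom, d001_nm = 5.838) {
  r_max <- min(geom$shape) / 2 - 2
  k <- 1L
  harmonic <- integer(0); r_px <- numeric(0)
  repeat {
    d <- d001_nm / k
    if (2 * d <= geom$wavelength_nm) break
    r <- d_to_radius(d, geom)
    if (r > r_max) break
    harmonic <- c(harmonic, k); r_px <- c(r_px, r)
    k <- k + 1L
  }
  data.frame(harmonic = harmonic, d_nm = d001_nm / harmonic,
             q_nm = d_to_q(d001_nm / harmonic), r_px = r_px)
}
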
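#' Structural model of a claw-keratin fiber-diffraction pattern
#'
#' Parameterizes the expected (noise-free) intensity surface of one detector
#' frame: an amorphous background decaying with radius, an intense primary-beam
#' spot, and two diffraction arcs at the keratin periods d = 0.51 nm
#' (molecular packing) and d = 0.98 nm (intermolecular distance / orientation
#' of structural units). Each arc is a Gaussian in radius multiplied by an
#' angular profile with two antipodal lobes (fiber symmetry), plus an
#' isotropic ring sharing the same radial profile; \code{ring_fraction} is the
#' isotropic share of the arc's intensity. Hot and dead pixels and the raw
#' total-count range describe detector artifacts.
#'
#' Amplitudes are relative weights: when a pattern is rendered, the expected
#' surface is rescaled so its integral matches a target raw count drawn from
#' \code{total_counts_range}.
#'
#' @param arc_d_nm Periods of the two arcs, nm.
#' @param arc_amplitude Relative peak weight per arc (same order as
#'   \code{arc_d_nm}).
#' @param arc_radial_sigma Radial Gaussian width of each arc, px.
#' @param arc_angular_conc Angular concentration (von Mises-like, period
#'   180 deg) per arc; larger = better-oriented fibers.
#' @param ring_fraction Isotropic share of each arc's intensity, in [0, 1].
#' @param background_level Relative weight of the amorphous background.
#' @param background_scale Radial e-folding length of the background, px.
#' @param beam_amplitude Relative weight of the primary-beam spot.
#' @param beam_sigma Gaussian width of the beam spot, px.
#' @param hot_pixel_rate Fraction of pixels replaced by saturating outliers.
#' @param dead_pixel_rate Fraction of pixels forced to zero.
#' @param hot_value Count value written into hot pixels.
#' @param total_counts_range Raw integral-count range the instrument records.
#' @return An object of class \code{"structure_model"}.
#' @seealso \code{\link{default_structures}}, \code{\link{render_pattern}}
#' @export
structure_model <- function(arc_d_nm = c(0.98, 0.51),
                            arc_amplitude = c(1.0, 0.7),
                            arc_radial_sigma = c(3.5, 3.0),
                            arc_angular_conc = c(3.0, 2.5),
                            ring_fraction = c(0.25, 0.35),
                            background_level = 1.0,
                            background_scale = 55,
                            beam_amplitude = 400,
                            beam_sigma = 4,
                            hot_pixel_rate = 2e-4,
                            dead_pixel_rate = 1e-4,
                            hot_value = 65535,
                            total_counts_range = c(2e6, 1e7)) {
  stopifnot(length(arc_d_nm) == length(arc_amplitude),
            length(arc_d_nm) == length(arc_radial_sigma),
            length(arc_d_nm) == length(arc_angular_conc),
            length(arc_d_nm) == length(ring_fraction),
            all(arc_amplitude >= 0), all(arc_radial_sigma > 0),
            all(arc_angular_conc >= 0),
            all(ring_fraction >= 0), all(ring_fraction <= 1),
            background_level >= 0, background_scale > 0,
            beam_amplitude >= 0, beam_sigma > 0,
            hot_pixel_rate >= 0, hot_pixel_rate < 1,
            dead_pixel_rate >= 0, dead_pixel_rate < 1,
            length(total_counts_range) == 2,
            total_counts_range[1] > 0,
            total_counts_range[2] >= total_counts_range[1])
  structure(as.list(environment()), class = "structure_model")
}

#' Class-conditional structure pair for the synthetic cohort
#'
#' Returns the "no cancer" and "cancer" structural models used by the cohort
#' generator. The cancer effect follows the direction seen in group-averaged
#' difference images of real claw patterns: the oriented peaks at d = 0.98 nm
#' are suppressed while the isotropic ring at the same radius is more
#' pronounced, with a weaker same-direction change at d = 0.51 nm, and a mild
#' loss of orientation order. \code{effect} scales the displacement of every
#' affected parameter from its "no cancer" value: 0 gives identical classes
#' (a null cohort), 1 the default effect, larger values a stronger contrast.
#'
#' @param effect Non-negative effect-size multiplier.
#' @return \code{list(no_cancer =, cancer =)} of
#'   \code{\link{structure_model}} objects.
#' @export
default_structures <- function(effect = 1) {
  stopifnot(is.numeric(effect), length(effect) == 1, effect >= 0)
  base <- structure_model()
  lerp <- function(a, b) a + effect * (b - a)
  cancer <- structure_model(
    arc_amplitude   = lerp(base$arc_amplitude,   c(0.75, 0.60)),
    arc_angular_conc = lerp(base$arc_angular_conc, c(2.4, 2.1)),
    ring_fraction   = pmin(1, lerp(base$ring_fraction, c(0.45, 0.43))))
  list(no_cancer = base, cancer = cancer)
}

#' Cohort design for the synthetic study
#'
#' Describes the patient cohort the generator emulates: number of patients,
#' cancer prevalence, samples per patient (most patients contribute four
#' independently prepared claw shavings, a few drop to three), and the
#' probability that a sample taken from a cancer patient is structurally
#' unaffected (not all claw keratin changes during cancer development).
#' Labels are assigned per patient, never per sample.
#'
#' @param n_patients Number of patients.
#' @param cancer_prevalence Fraction of patients with cancer, in (0, 1).
#' @param samples_per_patient Modal number of samples per patient.
#' @param dropout_rate Probability a patient contributes one sample fewer.
#' @param unaffected_sample_rate Probability a cancer patient's sample is
#'   drawn from the non-cancer structural distribution.
#' @param seed Integer RNG seed for cohort generation.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_patients = 265,
                        cancer_prevalence = 104 / 265,
                        samples_per_patient = 4,
                        dropout_rate = 0.15,
                        unaffected_sample_rate = 0.15,
                        seed = 20240630) {
  if (!(cancer_prevalence > 0 && cancer_prevalence < 1))
    stop("cancer_prevalence must lie strictly inside (0, 1)")
  stopifnot(n_patients >= 2, samples_per_patient >= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            unaffected_sample_rate >= 0, unaffected_sample_rate <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 cancer_prevalence = cancer_prevalence,
                 samples_per_patient = as.integer(samples_per_patient),
                 dropout_rate = dropout_rate,
                 unaffected_sample_rate = unaffected_sample_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}
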
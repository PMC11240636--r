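#' Plan a synthetic claw-XRD cohort
#'
#' Draws every latent quantity of a synthetic cohort up front — patient
#' labels at the stated prevalence, samples per patient, per-sample fiber
#' orientation (uniform), raw total counts (uniform in the instrument's
#' 2-10 mln range), batch assignment, biological variability multipliers and
#' the per-sample render seed — without rendering any image. Frames are then
#' materialized one at a time with \code{\link{render_cohort_sample}}, so
#' arbitrarily large cohorts stream through the pipeline.
#'
#' Biological variability has two levels, both acting on the structural
#' parameters that carry the disease signature so that patients genuinely
#' overlap between classes. Per patient (shared by all of a patient's
#' shavings): an independent lognormal multiplier on each arc's amplitude
#' (sd \code{patient_sd}), a clipped Gaussian perturbation of each arc's
#' ring fraction (sd \code{patient_ring_sd}), and a lognormal multiplier on
#' orientation concentration (sd \code{patient_conc_sd}). Per sample: a
#' lognormal amplitude multiplier shared across arcs (sd \code{sample_sd},
#' shaving thickness/placement), a smaller ring-fraction perturbation
#' (sd \code{ring_jitter_sd}) and a concentration multiplier. A sample from
#' a cancer patient falls back to the non-cancer structural distribution
#' with probability \code{spec$unaffected_sample_rate} (not all claw
#' keratin is altered by the disease).
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param structures Class-conditional pair from
#'   \code{\link{default_structures}}.
#' @param geom A \code{\link{detector_geometry}}.
#' @param patient_sd Lognormal sd of the per-arc patient amplitude
#'   multipliers.
#' @param patient_ring_sd Sd of the patient-level ring-fraction
#'   perturbation.
#' @param patient_conc_sd Lognormal sd of the patient-level concentration
#'   multiplier.
#' @param sample_sd Lognormal sd of the sample-level amplitude multiplier.
#' @param ring_jitter_sd Sd of the sample-level ring-fraction perturbation.
#' @param batch_size Samples per measurement batch (one AgBH calibration
#'   frame per batch).
#' @return A \code{"cohort_plan"}: list with \code{manifest} (one row per
#'   sample: sample_id, patient_id, label, batch_id, plus latent columns),
#'   \code{structures}, \code{geom}, \code{spec}.
#' @export
plan_cohort <- function(spec, structures = default_structures(),
                        geom = detector_geometry(),
                        patient_sd = 0.20, patient_ring_sd = 0.14,
                        patient_conc_sd = 0.15, sample_sd = 0.15,
                        ring_jitter_sd = 0.05, batch_size = 120) {
  stopifnot(inherits(spec, "cohort_spec"),
            is.list(structures),
            all(c("no_cancer", "cancer") %in% names(structures)),
            inherits(geom, "detector_geometry"))
  with_local_seed(spec$seed, {
    n_cancer <- round(spec$n_patients * spec$cancer_prevalence)
    labels_pat <- rep("no_cancer", spec$n_patients)
    labels_pat[sample.int(spec$n_patients, n_cancer)] <- "cancer"
    pat_ids <- sprintf("P%03d", seq_len(spec$n_patients))
    n_samp <- pmax(1L, spec$samples_per_patient -
                     stats::rbinom(spec$n_patients, 1L, spec$dropout_rate))
    np <- spec$n_patients
    pat_amp_098 <- exp(stats::rnorm(np, 0, patient_sd))
    pat_amp_051 <- exp(stats::rnorm(np, 0, patient_sd))
    pat_ring_098 <- stats::rnorm(np, 0, patient_ring_sd)
    pat_ring_051 <- stats::rnorm(np, 0, patient_ring_sd)
    pat_conc <- exp(stats::rnorm(np, 0, patient_conc_sd))

    idx_pat <- rep(seq_len(spec$n_patients), n_samp)
    n <- length(idx_pat)
    manifest <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      patient_id = pat_ids[idx_pat],
      label = labels_pat[idx_pat],
      batch_id = sprintf("B%02d", (seq_len(n) - 1) %/% batch_size + 1),
      path = NA_character_,
      stringsAsFactors = FALSE)
    manifest$orientation_deg <- stats::runif(n, 0, 180)
    manifest$total_counts <- stats::runif(n, structures$no_cancer$total_counts_range[1],
                                          structures$no_cancer$total_counts_range[2])
    manifest$unaffected <- manifest$label == "cancer" &
      stats::runif(n) < spec$unaffected_sample_rate
    samp_mult <- exp(stats::rnorm(n, 0, sample_sd))
    manifest$amp_mult_098 <- pat_amp_098[idx_pat] * samp_mult
    manifest$amp_mult_051 <- pat_amp_051[idx_pat] * samp_mult
    manifest$conc_mult <- pat_conc[idx_pat] * exp(stats::rnorm(n, 0, 0.10))
    manifest$ring_jit_098 <- pat_ring_098[idx_pat] +
      stats::rnorm(n, 0, ring_jitter_sd)
    manifest$ring_jit_051 <- pat_ring_051[idx_pat] +
      stats::rnorm(n, 0, ring_jitter_sd)
    manifest$render_seed <- sample.int(.Machine$integer.max - 1L, n)

    structure(list(manifest = manifest, structures = structures,
                   geom = geom, spec = spec),
              class = "cohort_plan")
  })
}

# effective structural model of one planned sample; arc order (0.98, 0.51)
sample_structure <- function(plan, i) {
  row <- plan$manifest[i, ]
  base <- if (row$label == "cancer" && !row$unaffected)
    plan$structures$cancer else plan$structures$no_cancer
  i98 <- which(base$arc_d_nm == 0.98); i51 <- which(base$arc_d_nm == 0.51)
  mult <- numeric(length(base$arc_d_nm)) + 1
  jit <- numeric(length(base$arc_d_nm))
  mult[i98] <- row$amp_mult_098; mult[i51] <- row$amp_mult_051
  jit[i98] <- row$ring_jit_098; jit[i51] <- row$ring_jit_051
  base$arc_amplitude <- base$arc_amplitude * mult
  base$arc_angular_conc <- base$arc_angular_conc * row$conc_mult
  base$ring_fraction <- pmin(0.95, pmax(0.02, base$ring_fraction + jit))
  base
}

#' Render one sample of a planned cohort
#'
#' @param plan A \code{\link{plan_cohort}} result.
#' @param i Row index into \code{plan$manifest}.
#' @return A \code{raw_image} carrying the sample's identity and label.
#' @export
render_cohort_sample <- function(plan, i) {
  stopifnot(inherits(plan, "cohort_plan"),
            i >= 1, i <= nrow(plan$manifest))
  row <- plan$manifest[i, ]
  render_pattern(sample_structure(plan, i), plan$geom,
                 orientation_deg = row$orientation_deg,
                 seed = row$render_seed,
                 total_counts = row$total_counts,
                 sample_id = row$sample_id, patient_id = row$patient_id,
                 batch_id = row$batch_id, label = row$label)
}

#' Render the AgBH calibration frame of a batch
#'
#' One calibration frame per measurement batch, seeded from the cohort seed
#' and the batch index so repeated runs are identical.
#'
#' @inheritParams render_cohort_sample
#' @param batch_id Batch identifier as it appears in the manifest.
#' @return A \code{raw_image} of concentric AgBH rings.
#' @export
render_cohort_agbh <- function(plan, batch_id) {
  stopifnot(inherits(plan, "cohort_plan"),
            batch_id %in% plan$manifest$batch_id)
  k <- as.integer(sub("^B", "", batch_id))
  render_agbh(plan$geom, seed = (plan$spec$seed + 7919L * k) %% .Machine$integer.max,
              batch_id = batch_id)
}

#' Generate a synthetic cohort, optionally writing it to disk
#'
#' Materializes every frame of a \code{\link{plan_cohort}} design. With
#' \code{dir = NULL} the images are returned in memory; otherwise each frame
#' and each batch's AgBH calibration frame are written (text-matrix or TIFF
#' dialect) together with a manifest CSV
#' (\code{sample_id,patient_id,label,batch_id,path}).
#'
#' @inheritParams plan_cohort
#' @param dir Output directory, or \code{NULL} for an in-memory cohort.
#' @param format \code{"text"} or \code{"tiff"} (see
#'   \code{\link{write_image}}).
#' @return List with \code{manifest}, \code{plan}, and \code{images} (list of
#'   \code{raw_image}, \code{NULL} when written to disk).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            structures = default_structures(),
                            geom = detector_geometry(),
                            dir = NULL, format = c("text", "tiff"), ...) {
  format <- match.arg(format)
  plan <- plan_cohort(spec, structures, geom, ...)
  n <- nrow(plan$manifest)
  images <- NULL
  if (is.null(dir)) {
    images <- lapply(seq_len(n), function(i) render_cohort_sample(plan, i))
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "text") ".txt" else ".tif"
    for (i in seq_len(n)) {
      path <- file.path(dir, paste0(plan$manifest$sample_id[i], ext))
      write_image(render_cohort_sample(plan, i), path, format = format)
      plan$manifest$path[i] <- path
    }
    for (b in unique(plan$manifest$batch_id))
      write_image(render_cohort_agbh(plan, b),
                  file.path(dir, paste0("agbh_", b, ext)), format = format)
    write_manifest(plan$manifest[, c("sample_id", "patient_id", "label",
                                     "batch_id", "path")],
                   file.path(dir, "manifest.csv"))
  }
  list(manifest = plan$manifest, plan = plan, images = images)
}
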
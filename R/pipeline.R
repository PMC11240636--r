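#' Configuration of a full synthetic-study run
#'
#' One flat object holding every tunable of the end-to-end run: cohort
#' design, class effect size, detector geometry, preprocessing parameters,
#' feature parameters, the classifier grid, the feature-group experiments to
#' run, and all seeds. Every paper-gap default is an explicit key; the run
#' directory always receives the exact config that produced it.
#'
#' @param n_patients,cancer_prevalence,samples_per_patient,dropout_rate,unaffected_sample_rate
#'   Cohort design (see \code{\link{cohort_spec}}).
#' @param effect Class effect-size multiplier (see
#'   \code{\link{default_structures}}).
#' @param geom A \code{\link{detector_geometry}}.
#' @param preprocess A \code{\link{preprocess_config}}.
#' @param feature_order Fourier series order N.
#' @param radial_width,circular_width Profile band/annulus widths, px.
#' @param experiments Feature groups to evaluate (subset of
#'   \code{c("radial", "circular", "both")}).
#' @param grid Classifier hyperparameter grid.
#' @param n_folds CV folds.
#' @param test_fraction Blind-set patient fraction.
#' @param calibrate Run AgBH calibration per batch.
#' @param qc_max_repaired Reject frames with a larger repaired-pixel
#'   fraction.
#' @param qc_reject_isotropic Reject frames whose angular distribution is
#'   flat.
#' @param seed Master seed; cohort, split and classifier seeds derive from
#'   it.
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(n_patients = 265,
                       cancer_prevalence = 104 / 265,
                       samples_per_patient = 4,
                       dropout_rate = 0.15,
                       unaffected_sample_rate = 0.15,
                       effect = 1,
                       geom = detector_geometry(),
                       preprocess = preprocess_config(),
                       feature_order = 10,
                       radial_width = 5,
                       circular_width = 5,
                       experiments = c("radial", "circular", "both"),
                       grid = default_grid(),
                       n_folds = 10,
                       test_fraction = 68 / 265,
                       calibrate = TRUE,
                       qc_max_repaired = 0.01,
                       qc_reject_isotropic = TRUE,
                       seed = 20240630) {
  experiments <- match.arg(experiments, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the complete synthetic study end-to-end
#'
#' simulate -> preprocess -> features -> patient-level split -> train ->
#' predict -> aggregate -> metrics, streaming one frame at a time so memory
#' stays flat. Per batch, an AgBH frame is rendered and its calibration
#' measured once. Frames failing quality control (centering failure,
#' isotropy flag, excess repaired pixels) are rejected with a logged reason,
#' mirroring the quality-control rejection of real acquisitions. For each
#' configured feature-group experiment a classifier is trained on the
#' training patients and evaluated on the blind patients at sample and
#' patient level; group-averaged training images ("cancer", "no cancer",
#' difference) are accumulated as a structural diagnostic.
#'
#' Deterministic: identical config (including seeds) gives identical
#' metrics.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Optional directory: writes manifest, preprocessing log,
#'   feature table, predictions, metrics JSON, mean-image matrices, ROC and
#'   threshold-sweep plots, and the config itself.
#' @param verbose Print stage progress.
#' @return List: \code{manifest}, \code{qc}, \code{features}, \code{split},
#'   \code{experiments} (per group: classifier, sample/patient predictions
#'   and \code{metrics_report}s), \code{mean_images}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = interactive()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- cohort_spec(n_patients = config$n_patients,
                      cancer_prevalence = config$cancer_prevalence,
                      samples_per_patient = config$samples_per_patient,
                      dropout_rate = config$dropout_rate,
                      unaffected_sample_rate = config$unaffected_sample_rate,
                      seed = config$seed)
  plan <- plan_cohort(spec, default_structures(config$effect), config$geom)
  n <- nrow(plan$manifest)
  say("cohort: %d samples from %d patients", n, spec$n_patients)

  calib <- list()
  if (config$calibrate) {
    for (b in unique(plan$manifest$batch_id))
      calib[[b]] <- calibrate_scale(render_cohort_agbh(plan, b), config$geom,
                                    harmonic = config$preprocess$calib_harmonic,
                                    tolerance = config$preprocess$calib_tolerance)
  }

  feats <- vector("list", n)
  qc <- data.frame(sample_id = plan$manifest$sample_id,
                   accepted = FALSE, reason = "", rotation_deg = NA_real_,
                   n_repaired = NA_integer_, scale_factor = NA_real_,
                   center_row = NA_real_, center_col = NA_real_,
                   stringsAsFactors = FALSE)
  shape <- config$geom$shape
  sums <- list(cancer = matrix(0, shape[1], shape[2]),
               no_cancer = matrix(0, shape[1], shape[2]))
  counts_by_class <- c(cancer = 0L, no_cancer = 0L)
  split <- split_patients(plan$manifest, config$test_fraction,
                          seed = config$seed + 1L)

  for (i in seq_len(n)) {
    row <- plan$manifest[i, ]
    img <- render_cohort_sample(plan, i)
    pimg <- tryCatch(
      preprocess_image(img, config$geom,
                       calibration = calib[[row$batch_id]],
                       config = config$preprocess),
      error = function(e) e)
    if (inherits(pimg, "error")) {
      qc$reason[i] <- conditionMessage(pimg)
      next
    }
    qc$rotation_deg[i] <- pimg$rotation_deg
    qc$n_repaired[i] <- pimg$n_repaired
    qc$scale_factor[i] <- pimg$scale_factor
    qc$center_row[i] <- pimg$raw_center_px[1]
    qc$center_col[i] <- pimg$raw_center_px[2]
    if (config$qc_reject_isotropic && pimg$flags$isotropic) {
      qc$reason[i] <- "isotropic pattern"
      next
    }
    if (pimg$flags$repaired_fraction > config$qc_max_repaired) {
      qc$reason[i] <- "excess repaired pixels"
      next
    }
    fv <- build_feature_vector(pimg, features = "both",
                               order = config$feature_order,
                               radial_width = config$radial_width,
                               circular_width = config$circular_width)
    feats[[i]] <- cbind(
      data.frame(sample_id = row$sample_id, patient_id = row$patient_id,
                 label = row$label, stringsAsFactors = FALSE),
      as.data.frame(as.list(fv), check.names = FALSE))
    qc$accepted[i] <- TRUE
    if (row$patient_id %in% split$train_patients) {
      sums[[row$label]] <- sums[[row$label]] + pimg$intensity
      counts_by_class[row$label] <- counts_by_class[row$label] + 1L
    }
    if (i %% 200 == 0) say("  processed %d / %d frames", i, n)
  }
  features <- do.call(rbind, feats[!vapply(feats, is.null, logical(1))])
  say("accepted %d / %d frames after QC", sum(qc$accepted), n)

  mean_images <- list(
    cancer = sums$cancer / max(1L, counts_by_class["cancer"]),
    no_cancer = sums$no_cancer / max(1L, counts_by_class["no_cancer"]))
  mean_images$difference <- mean_images$no_cancer - mean_images$cancer

  experiments <- list()
  for (ex in config$experiments) {
    cols <- feature_names(ex, config$feature_order)
    df <- features[, c("sample_id", "patient_id", "label", cols)]
    train_df <- df[df$patient_id %in% split$train_patients, ]
    test_df <- df[df$patient_id %in% split$test_patients, ]
    say("experiment '%s': %d features, %d train / %d test samples",
        ex, length(cols), nrow(train_df), nrow(test_df))
    clf <- fit_classifier(train_df, grid = config$grid,
                          n_folds = config$n_folds,
                          seed = config$seed + 2L)
    sample_preds <- predict_samples(clf, test_df)
    patient_preds <- aggregate_patients(sample_preds, method = "mean_prob")
    experiments[[ex]] <- list(
      classifier = clf,
      sample_preds = sample_preds,
      patient_preds = patient_preds,
      sample_metrics = compute_metrics(sample_preds),
      patient_metrics = compute_metrics(patient_preds))
    say("  sample AUC %.3f, patient AUC %.3f",
        experiments[[ex]]$sample_metrics$auc,
        experiments[[ex]]$patient_metrics$auc)
  }

  result <- list(manifest = plan$manifest, qc = qc, features = features,
                 split = split, experiments = experiments,
                 mean_images = mean_images, config = config)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

# persist a run: every artifact regenerable from config + seeds
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg$geom <- unclass(cfg$geom)
  cfg$preprocess <- unclass(cfg$preprocess)
  jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(result$manifest[, c("sample_id", "patient_id", "label",
                                     "batch_id", "path")],
                 file.path(out_dir, "manifest.csv"))
  utils::write.csv(result$qc, file.path(out_dir, "preprocessing_log.csv"),
                   row.names = FALSE)
  utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  for (cls in names(result$mean_images))
    utils::write.table(result$mean_images[[cls]],
                       file.path(out_dir, sprintf("mean_image_%s.txt", cls)),
                       row.names = FALSE, col.names = FALSE)
  metrics <- list()
  for (ex in names(result$experiments)) {
    e <- result$experiments[[ex]]
    utils::write.csv(e$sample_preds,
                     file.path(out_dir, sprintf("sample_predictions_%s.csv", ex)),
                     row.names = FALSE)
    utils::write.csv(e$patient_preds,
                     file.path(out_dir, sprintf("patient_predictions_%s.csv", ex)),
                     row.names = FALSE)
    metrics[[ex]] <- list(
      best_params = as.list(e$classifier$best_params),
      mean_cv_auc = max(e$classifier$cv_table$mean_cv_auc),
      sample_auc = e$sample_metrics$auc,
      patient_auc = e$patient_metrics$auc,
      best_operating_point = as.list(e$patient_metrics$best))
    plot_experiment(e, ex, out_dir)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

plot_experiment <- function(e, name, out_dir) {
  grDevices::png(file.path(out_dir, sprintf("roc_%s.png", name)),
                 width = 600, height = 600)
  graphics::plot(e$sample_metrics$roc$fpr, e$sample_metrics$roc$tpr,
                 type = "l", col = "orange", lwd = 2,
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (%s features)", name))
  graphics::lines(e$patient_metrics$roc$fpr, e$patient_metrics$roc$tpr,
                  col = "blue", lwd = 2)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright",
                   sprintf(c("samples AUC %.2f", "patients AUC %.2f"),
                           c(e$sample_metrics$auc, e$patient_metrics$auc)),
                   col = c("orange", "blue"), lwd = 2)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, sprintf("threshold_sweep_%s.png", name)),
                 width = 700, height = 500)
  tt <- e$patient_metrics$threshold_table
  graphics::plot(tt$threshold, tt$specificity, type = "l", col = "darkgreen",
                 lwd = 2, ylim = c(0, 1), xlab = "mean probability threshold",
                 ylab = "metric",
                 main = sprintf("threshold sweep, patients (%s features)", name))
  graphics::lines(tt$threshold, tt$sensitivity, col = "red", lwd = 2)
  graphics::lines(tt$threshold, tt$balanced_accuracy, col = "black", lwd = 2)
  graphics::legend("bottomleft", c("specificity", "sensitivity", "balanced accuracy"),
                   col = c("darkgreen", "red", "black"), lwd = 2)
  grDevices::dev.off()
  invisible(NULL)
}

#' Preprocess and featurize frames listed in a manifest (real-data mode)
#'
#' Reads each frame from \code{manifest$path} (TIFF or text matrix),
#' preprocesses it — using one AgBH calibration per batch when
#' \code{agbh_paths} supplies them — and extracts the canonical feature
#' table. Entry point for measured (non-synthetic) cohorts.
#'
#' @param manifest Data frame with \code{sample_id, patient_id, label,
#'   batch_id, path}.
#' @param geom A \code{\link{detector_geometry}}.
#' @param agbh_paths Named character vector, batch_id -> AgBH frame path.
#' @param config A \code{\link{preprocess_config}}.
#' @param ... Passed to \code{\link{build_feature_vector}}.
#' @return List: \code{features} data frame, \code{qc} log.
#' @export
process_manifest <- function(manifest, geom = detector_geometry(),
                             agbh_paths = NULL,
                             config = preprocess_config(), ...) {
  calib <- list()
  if (!is.null(agbh_paths))
    for (b in names(agbh_paths))
      calib[[b]] <- calibrate_scale(read_image(agbh_paths[[b]],
                                               expect_shape = geom$shape),
                                    geom, harmonic = config$calib_harmonic,
                                    tolerance = config$calib_tolerance)
  rows <- list(); qc <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    img <- read_image(m$path, expect_shape = geom$shape,
                      sample_id = m$sample_id, patient_id = m$patient_id,
                      batch_id = m$batch_id, label = m$label)
    pimg <- tryCatch(
      preprocess_image(img, geom, calibration = calib[[m$batch_id]],
                       config = config),
      error = function(e) e)
    if (inherits(pimg, "error")) {
      qc[[i]] <- data.frame(sample_id = m$sample_id, accepted = FALSE,
                            reason = conditionMessage(pimg))
      next
    }
    qc[[i]] <- data.frame(sample_id = m$sample_id, accepted = TRUE,
                          reason = "")
    fv <- build_feature_vector(pimg, ...)
    rows[[i]] <- cbind(
      data.frame(sample_id = m$sample_id, patient_id = m$patient_id,
                 label = m$label, stringsAsFactors = FALSE),
      as.data.frame(as.list(fv), check.names = FALSE))
  }
  list(features = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       qc = do.call(rbind, qc))
}
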
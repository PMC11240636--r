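# Shared fixtures, built once per test run and memoized: rendering a frame
# and preprocessing it are the expensive steps, and many tests can share the
# same seeded frames.
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fix_geom <- function() memo("geom", detector_geometry())

# defect-free structural models (defects are opted into explicitly)
fix_structure <- function(class = "no_cancer", clean = TRUE) {
  key <- paste0("struct_", class, "_", clean)
  memo(key, {
    s <- default_structures()[[class]]
    if (clean) {
      s$hot_pixel_rate <- 0
      s$dead_pixel_rate <- 0
    }
    s
  })
}

fix_pattern <- function(orientation = 37, seed = 42, class = "no_cancer",
                        clean = TRUE, total_counts = 5e6) {
  key <- sprintf("pat_%s_%s_%s_%s_%s", orientation, seed, class, clean,
                 total_counts)
  memo(key, render_pattern(fix_structure(class, clean), fix_geom(),
                           orientation_deg = orientation, seed = seed,
                           total_counts = total_counts))
}

fix_preprocessed <- function(orientation = 37, seed = 42,
                             class = "no_cancer", clean = TRUE,
                             total_counts = 5e6) {
  key <- sprintf("pre_%s_%s_%s_%s_%s", orientation, seed, class, clean,
                 total_counts)
  memo(key, suppressWarnings(
    preprocess_image(fix_pattern(orientation, seed, class, clean,
                                 total_counts), fix_geom())))
}

# an isotropic frame: rings only, no oriented component
fix_isotropic <- function(seed = 5) {
  memo(paste0("iso_", seed), {
    s <- fix_structure()
    s$ring_fraction <- c(1, 1)
    render_pattern(s, fix_geom(), orientation_deg = 0, seed = seed,
                   total_counts = 5e6)
  })
}

new_raw_image_for_test <- function(m) clawxrd:::new_raw_image(m)

# independent AUC oracle: Mann-Whitney U with midranks
auc_mann_whitney <- function(truth, score) {
  truth <- as.logical(truth)
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# synthetic feature table for classifier tests (no imaging involved):
# two Gaussian classes, patient random effect, several samples per patient
make_feature_table <- function(n_patients = 60, delta = 1, p = 8, seed = 1,
                               samples = 4) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_patients)) {
    lab <- if (i <= n_patients / 2) "cancer" else "no_cancer"
    mu <- (if (lab == "cancer") delta else 0) + rnorm(p, 0, 0.3)
    for (j in seq_len(samples)) {
      x <- mu + rnorm(p)
      row <- as.data.frame(as.list(x))
      names(row) <- sprintf("f%02d", seq_len(p))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(sample_id = sprintf("S%03d_%d", i, j),
                   patient_id = sprintf("P%03d", i), label = lab,
                   stringsAsFactors = FALSE), row)
    }
  }
  do.call(rbind, rows)
}
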
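# ---- low-level resampling ---------------------------------------------------

# Vectorized bilinear lookup at fractional 0-based (ys, xs). A target sample
# is valid only if every neighbor with nonzero weight is in range and valid,
# so repaired/cropped source pixels never leak into interpolated values.
bilinear_at <- function(mat, valid, ys, xs) {
  nr <- nrow(mat); nc <- ncol(mat)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  val <- numeric(length(ys))
  ok <- rep(TRUE, length(ys))
  dys <- c(0, 0, 1, 1); dxs <- c(0, 1, 0, 1)
  for (j in 1:4) {
    yy <- y0 + dys[j]; xx <- x0 + dxs[j]
    w <- (if (dys[j] == 0) 1 - fy else fy) * (if (dxs[j] == 0) 1 - fx else fx)
    inr <- yy >= 0 & yy < nr & xx >= 0 & xx < nc
    # clamp out-of-range indices to a dummy cell; they carry weight 0 below
    idx <- pmin.int(pmax.int(yy, 0), nr - 1) + 1 +
           pmin.int(pmax.int(xx, 0), nc - 1) * nr
    good <- if (is.null(valid)) inr else inr & valid[idx]
    ok <- ok & (good | w <= 1e-12)
    val <- val + w * mat[idx] * good
  }
  val[!ok] <- 0
  list(values = val, ok = ok)
}

# ---- centering --------------------------------------------------------------

#' Locate the beam center of a detector frame
#'
#' Two-stage estimate: the intensity centroid of the (outlier-clipped)
#' central region seeds a refinement that exploits the inversion symmetry of
#' a fiber-diffraction pattern — both marginal sums of an inversion-symmetric
#' image are mirror-symmetric about the beam center, so each coordinate is
#' found by minimizing the squared mismatch between the marginal profile and
#' its reflection.
#'
#' @param img A \code{raw_image} or bare matrix.
#' @param refine_halfwidth Search half-width around the centroid, px.
#' @return Fractional 0-based \code{c(row, col)} beam center.
#' @export
find_center <- function(img, refine_halfwidth = 3) {
  m <- if (inherits(img, "raw_image")) img$counts else img
  stopifnot(is.matrix(m))
  # clip saturating outliers so stray hot pixels cannot drag the estimate
  cap <- stats::quantile(m, 0.9995, names = FALSE)
  mc <- pmin(m, cap)
  nr <- nrow(mc); nc <- ncol(mc)
  qr <- (nr %/% 4):(3 * nr %/% 4); qc <- (nc %/% 4):(3 * nc %/% 4)
  centw <- mc[qr, qc]
  centw <- pmax(centw - stats::median(centw), 0)
  if (sum(centw) <= 0) stop("centering failure: no central intensity found")
  cy <- sum(rowSums(centw) * (qr - 1)) / sum(centw)
  cx <- sum(colSums(centw) * (qc - 1)) / sum(centw)
  if (cy < nr / 4 || cy > 3 * nr / 4 || cx < nc / 4 || cx > 3 * nc / 4)
    stop("centering failure: centroid outside the central quarter of the detector")
  refl_refine <- function(s, c0) {
    x <- seq_along(s) - 1
    cand <- seq(c0 - refine_halfwidth, c0 + refine_halfwidth, by = 0.02)
    obj <- vapply(cand, function(cc) {
      xr <- 2 * cc - x
      keep <- xr >= 0 & xr <= length(s) - 1
      sr <- stats::approx(x, s, xout = xr[keep])$y
      mean((s[keep] - sr)^2)
    }, numeric(1))
    cand[which.min(obj)]
  }
  c(refl_refine(rowSums(mc), cy), refl_refine(colSums(mc), cx))
}

# ---- annulus statistics -----------------------------------------------------

# integer annulus id per pixel: half-open [r, r+1)
annulus_id <- function(shape, center) {
  g <- pixel_grid(shape, center)
  floor(g$r)
}

#' Azimuthally averaged radial profile
#'
#' Mean intensity per unit-width annulus \code{[r, r+1)} about a center,
#' over valid pixels only.
#'
#' @param mat Intensity matrix.
#' @param center Fractional \code{c(row, col)} center.
#' @param valid Optional logical matrix of usable pixels.
#' @return \code{data.frame(r, mean, n)} with \code{r} the annulus inner
#'   radius.
#' @export
azimuthal_profile <- function(mat, center, valid = NULL) {
  ann <- annulus_id(dim(mat), center)
  keep <- if (is.null(valid)) rep(TRUE, length(mat)) else as.vector(valid)
  ids <- ann[keep]; v <- mat[keep]
  s <- rowsum(v, ids); n <- rowsum(rep(1, length(v)), ids)
  data.frame(r = as.numeric(rownames(s)), mean = as.vector(s / n),
             n = as.vector(n))
}

# ---- AgBH scale calibration -------------------------------------------------

#' Measure the q-scale of a batch from its AgBH calibration frame
#'
#' The azimuthally averaged profile of the silver behenate frame is searched
#' near the radius predicted for one harmonic of the d(001) = 5.838 nm
#' lamellar period; the measured peak position (parabolic sub-pixel
#' refinement) against the predicted one gives the rescale factor
#' \code{scale_factor = expected / measured}. Matching common practice, the
#' rescale is only applied when the discrepancy exceeds \code{tolerance}
#' (default 3\%, the calibration spread below which the source study left
#' its data untouched).
#'
#' @param agbh AgBH calibration \code{raw_image}.
#' @param geom Nominal \code{\link{detector_geometry}}.
#' @param harmonic Which AgBH harmonic to measure (default 3).
#' @param tolerance Relative discrepancy below which no rescale is applied.
#' @param window Relative half-width of the search window around the
#'   predicted radius.
#' @return A \code{"calibration_result"}: measured and expected ring radii
#'   (px), \code{scale_factor}, and \code{applied}.
#' @export
calibrate_scale <- function(agbh, geom, harmonic = 3, tolerance = 0.03,
                            window = 0.15) {
  m <- if (inherits(agbh, "raw_image")) agbh$counts else agbh
  rings <- agbh_ring_radii(geom)
  if (!harmonic %in% rings$harmonic)
    stop("AgBH harmonic ", harmonic, " does not fall on the detector")
  expected <- rings$r_px[rings$harmonic == harmonic]
  center <- find_center(m)
  prof <- azimuthal_profile(m, center)
  win <- prof$r >= expected * (1 - window) & prof$r <= expected * (1 + window)
  if (sum(win) < 5) stop("calibration error: search window off the profile")
  pw <- prof[win, ]
  i <- which.max(pw$mean)
  # flatness test: peak prominence against the sampling noise of an
  # azimuthal mean (Poisson counts averaged over ~n pixels per annulus)
  floorlvl <- min(pw$mean)
  noise <- sqrt(max(floorlvl, 1) / stats::median(pw$n))
  if ((pw$mean[i] - floorlvl) < 6 * noise)
    stop("calibration error: no detectable AgBH ring near the predicted radius")
  # parabolic sub-pixel refinement on the annulus grid
  measured <- pw$r[i] + 0.5
  if (i > 1 && i < nrow(pw)) {
    y1 <- pw$mean[i - 1]; y2 <- pw$mean[i]; y3 <- pw$mean[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) measured <- measured + 0.5 * (y1 - y3) / denom
  }
  sf <- expected / measured
  structure(list(measured_ring_radius_px = measured,
                 expected_ring_radius_px = expected,
                 scale_factor = sf,
                 applied = abs(sf - 1) > tolerance,
                 harmonic = harmonic, tolerance = tolerance,
                 center_px = center),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> AgBH harmonic %d: measured %.2f px, expected %.2f px, scale %.4f (%s)\n",
              x$harmonic, x$measured_ring_radius_px, x$expected_ring_radius_px,
              x$scale_factor, if (x$applied) "applied" else "within tolerance, not applied"))
  invisible(x)
}

# ---- hot-pixel repair -------------------------------------------------------

# per-pixel trimmed neighborhood mean: average of the 4-neighbors excluding
# the largest (so one adjacent defect cannot mask another), edge-aware
neighbor_floor <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(dy, dx) {
    out <- matrix(NA_real_, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  n1 <- shift(1, 0); n2 <- shift(-1, 0); n3 <- shift(0, 1); n4 <- shift(0, -1)
  tot <- function(x) { x[is.na(x)] <- 0; x }
  cnt <- (!is.na(n1)) + (!is.na(n2)) + (!is.na(n3)) + (!is.na(n4))
  s <- tot(n1) + tot(n2) + tot(n3) + tot(n4)
  mx <- pmax(n1, n2, n3, n4, na.rm = TRUE)
  (s - mx) / pmax(cnt - 1, 1)
}

# per-annulus median and raw median absolute deviation by double sorting;
# groups are integer annulus ids
annulus_med_mad <- function(v, ann) {
  grp_median <- function(values) {
    o <- order(ann, values)
    len <- tabulate(ann[o] + 1L)
    len <- len[len > 0]
    ends <- cumsum(len); starts <- ends - len + 1L
    lo <- values[o][starts + (len - 1L) %/% 2L]
    hi <- values[o][starts + len %/% 2L]
    (lo + hi) / 2
  }
  med <- grp_median(v)
  ids <- sort(unique(ann))
  pos <- match(ann, ids)
  dev <- abs(v - med[pos])
  mad_raw <- grp_median(dev)
  list(ids = ids, pos = pos, median = med, mad = 1.4826 * mad_raw,
       n = tabulate(pos))
}

#' Detect and repair hot and dead pixels
#'
#' Detector defects are found against the radial structure of the pattern:
#' within each unit-width annulus about the beam center, pixels exceeding
#' the annulus median + \code{k} * MAD are candidate hot pixels, and
#' zero-count pixels are candidate dead pixels. Because diffraction arcs
#' make annulus intensity legitimately anisotropic, a spatial isolation veto
#' is applied on top of the annulus screen: a hot candidate must also tower
#' over its immediate neighborhood (single-pixel spike), and a dead
#' candidate must be an isolated zero whose neighbors clearly count photons.
#' Flagged pixels are replaced by the mean of the unflagged pixels on the
#' same annulus (the circle with the corresponding radius). Annuli with
#' fewer than \code{min_pixels} members are skipped with a warning.
#'
#' @param img \code{raw_image} or matrix.
#' @param center Beam center \code{c(row, col)}.
#' @param k MAD multiplier of the annulus hot threshold.
#' @param min_pixels Minimum annulus membership for repair.
#' @param grid Optional precomputed \code{pixel_grid} for \code{center}.
#' @return List: \code{counts} (repaired matrix), \code{repaired} (logical
#'   matrix), \code{n_hot}, \code{n_dead}, \code{skipped_annuli}.
#' @export
remove_hot_pixels <- function(img, center, k = 6, min_pixels = 8,
                              grid = NULL) {
  m <- if (inherits(img, "raw_image")) img$counts else img
  out <- m
  storage.mode(out) <- "double"
  if (is.null(grid)) grid <- pixel_grid(dim(m), center)
  ann <- floor(grid$r)
  v <- as.vector(m)
  st <- annulus_med_mad(v, as.integer(ann))
  small <- st$n < min_pixels
  med_px <- st$median[st$pos]
  mad_px <- st$mad[st$pos]
  nbr <- as.vector(neighbor_floor(m))
  hot <- v > med_px + k * mad_px & v > 4 * nbr + 10
  dead <- v == 0 & med_px > 9 & nbr >= 10
  bad <- (hot | dead) & !small[st$pos]
  repaired <- matrix(bad, nrow(m), ncol(m))
  if (any(bad)) {
    # annulus means over unflagged pixels
    keep <- !bad
    s <- rowsum((v * keep)[TRUE], st$pos)
    nk <- rowsum(as.numeric(keep), st$pos)
    amean <- as.vector(s) / pmax(as.vector(nk), 1)
    out[repaired] <- amean[st$pos[bad]]
  }
  if (any(small))
    warning(sprintf("hot-pixel repair skipped %d annuli with < %d pixels",
                    sum(small), min_pixels))
  list(counts = out, repaired = repaired,
       n_hot = sum(bad & v > 0), n_dead = sum(bad & v == 0),
       skipped_annuli = st$ids[small])
}

# ---- cropping ---------------------------------------------------------------

#' Validity mask for central-spot and circular cropping
#'
#' Marks as invalid the central region below \code{q_min} (the primary-beam
#' spot and anything under the recorded q-window floor) and everything
#' outside the inscribed disk around the given center (circular crop of the
#' detector corners).
#'
#' @param shape Detector dimensions.
#' @param center Beam center \code{c(row, col)}.
#' @param geom A \code{\link{detector_geometry}}.
#' @param q_min Lower q cut, nm^-1.
#' @return Logical matrix, \code{TRUE} for retained pixels.
#' @export
crop_mask <- function(shape, center, geom, q_min = 2) {
  g <- pixel_grid(shape, center)
  r_min <- q_to_radius(q_min, geom)
  r_disk <- min(center[1], center[2], shape[1] - 1 - center[1],
                shape[2] - 1 - center[2])
  g$r >= r_min & g$r <= r_disk
}

# ---- rotation alignment -----------------------------------------------------

#' Estimate the fiber orientation of a pattern
#'
#' Circular mean (period 180 deg) of the intensity distribution on the
#' annulus at the d = 0.98 nm radius, the stronger-anisotropy arc. The
#' isotropic floor is removed by subtracting the annulus median before
#' averaging. Returns \code{NA} with an isotropy flag when the angular
#' distribution is flat (resultant length below \code{iso_threshold}).
#'
#' @param mat Intensity matrix (centered not required; center given).
#' @param center Beam center.
#' @param geom Geometry (fixes the 0.98 nm radius).
#' @param valid Optional validity mask.
#' @param width Annulus width, px.
#' @param iso_threshold Minimum resultant length to accept an orientation.
#' @return List: \code{orientation_deg} (in [0, 180) or \code{NA}),
#'   \code{resultant}, \code{isotropic}.
#' @export
pattern_orientation <- function(mat, center, geom, valid = NULL, width = 5,
                                iso_threshold = 0.1, grid = NULL) {
  g <- if (is.null(grid)) pixel_grid(dim(mat), center) else grid
  r0 <- d_to_radius(0.98, geom)
  sel <- abs(g$r - r0) <= width / 2
  if (!is.null(valid)) sel <- sel & valid
  v <- mat[sel]; th <- g$theta[sel] * pi / 180
  w <- pmax(v - stats::median(v), 0)
  if (sum(w) <= 0)
    return(list(orientation_deg = NA_real_, resultant = 0, isotropic = TRUE))
  cs <- sum(w * cos(2 * th)) / sum(w)
  sn <- sum(w * sin(2 * th)) / sum(w)
  res <- sqrt(cs^2 + sn^2)
  if (res < iso_threshold)
    return(list(orientation_deg = NA_real_, resultant = res, isotropic = TRUE))
  list(orientation_deg = (atan2(sn, cs) / 2 * 180 / pi) %% 180,
       resultant = res, isotropic = FALSE)
}

# ---- the full chain ---------------------------------------------------------

#' Preprocessing parameters
#'
#' @param q_min Central-spot crop floor, nm^-1.
#' @param hot_k MAD multiplier for hot-pixel detection.
#' @param calib_tolerance Relative q-scale spread tolerated without rescale.
#' @param calib_harmonic AgBH harmonic used for calibration.
#' @param rot_annulus_width Annulus width for orientation estimation, px.
#' @param iso_threshold Resultant-length floor below which a pattern is
#'   declared isotropic (no rotation applied).
#' @param target_counts Standardized total intensity, counts.
#' @return A named list of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(q_min = 2, hot_k = 6, calib_tolerance = 0.03,
                              calib_harmonic = 3, rot_annulus_width = 5,
                              iso_threshold = 0.1, target_counts = 5e6) {
  structure(as.list(environment()), class = "preprocess_config")
}

#' Preprocess one raw detector frame
#'
#' The standardization chain applied identically to every frame, in order:
#' optional AgBH q-scale calibration (applied only beyond its tolerance),
#' beam-center location, hot/dead-pixel repair, central-spot crop at the
#' q-window floor plus circular crop of the corners, rotation of the pattern
#' so the fiber orientation lies on the vertical axis, and rescaling of the
#' total unmasked intensity to exactly \code{target_counts} (5 mln counts by
#' default). Recentering, rotation and any calibration rescale are combined
#' into a single bilinear resampling onto a grid centered at the geometric
#' detector center, so each retained pixel is interpolated once; any output
#' pixel whose interpolation neighborhood touches a repaired or out-of-range
#' source pixel is masked.
#'
#' @param img A \code{raw_image}.
#' @param geom A \code{\link{detector_geometry}}.
#' @param agbh Optional AgBH \code{raw_image} for this frame's batch.
#' @param calibration Optional precomputed \code{\link{calibrate_scale}}
#'   result for the batch (takes precedence over \code{agbh}).
#' @param config A \code{\link{preprocess_config}}.
#' @return A \code{"preprocessed_image"}: \code{intensity} (masked pixels 0),
#'   \code{valid} mask, \code{center_px} (grid center after recentering),
#'   \code{raw_center_px}, \code{rotation_deg}, \code{scale_factor},
#'   \code{standardize_scalar}, repair counts, QC \code{flags}, and the
#'   frame's identity fields.
#' @export
preprocess_image <- function(img, geom = detector_geometry(), agbh = NULL,
                             calibration = NULL,
                             config = preprocess_config()) {
  stopifnot(inherits(img, "raw_image"),
            all(dim(img$counts) == geom$shape))
  scale_factor <- 1
  if (is.null(calibration) && !is.null(agbh)) {
    calibration <- calibrate_scale(agbh, geom,
                                   harmonic = config$calib_harmonic,
                                   tolerance = config$calib_tolerance)
  }
  if (!is.null(calibration) && calibration$applied)
    scale_factor <- calibration$scale_factor
  center <- find_center(img$counts)
  g_src <- pixel_grid(dim(img$counts), center)
  rep_res <- remove_hot_pixels(img$counts, center, k = config$hot_k,
                               grid = g_src)
  src <- rep_res$counts
  src_valid <- !rep_res$repaired
  ori <- pattern_orientation(src, center, geom, valid = src_valid,
                             width = config$rot_annulus_width,
                             iso_threshold = config$iso_threshold,
                             grid = g_src)
  rotation_deg <- if (ori$isotropic) 0 else {
    a <- (90 - ori$orientation_deg) %% 180
    if (a > 90) a - 180 else a
  }

  shape <- dim(src)
  c_geo <- (shape - 1) / 2
  g <- pixel_grid(shape, c_geo)
  a <- rotation_deg * pi / 180
  # source position: undo the rotation, undo the q-scale rescale, start at
  # the measured raw center
  xs <- (cos(a) * g$dx + sin(a) * g$dy) / scale_factor + center[2]
  ys <- (-sin(a) * g$dx + cos(a) * g$dy) / scale_factor + center[1]
  bl <- bilinear_at(src, src_valid, as.vector(ys), as.vector(xs))
  intensity <- matrix(bl$values, shape[1], shape[2])
  valid <- matrix(bl$ok, shape[1], shape[2]) &
    crop_mask(shape, c_geo, geom, q_min = config$q_min)
  intensity[!valid] <- 0

  total <- sum(intensity[valid])
  if (total <= 0) stop("standardization error: zero total intensity after masking")
  scalar <- config$target_counts / total
  intensity <- intensity * scalar

  structure(list(
    intensity = intensity, valid = valid,
    center_px = c_geo, raw_center_px = center,
    rotation_deg = rotation_deg, orientation = ori,
    scale_factor = scale_factor, calibration = calibration,
    standardize_scalar = scalar,
    n_repaired = sum(rep_res$repaired),
    flags = list(isotropic = ori$isotropic,
                 repaired_fraction = mean(rep_res$repaired)),
    geom = geom,
    sample_id = img$sample_id, patient_id = img$patient_id,
    batch_id = img$batch_id, label = img$label),
    class = "preprocessed_image")
}

#' @export
print.preprocessed_image <- function(x, ...) {
  cat(sprintf("<preprocessed_image> sample %s: rotation %.1f deg, %d repaired px, sum %.0f over %d valid px\n",
              x$sample_id, x$rotation_deg, x$n_repaired,
              sum(x$intensity[x$valid]), sum(x$valid)))
  invisible(x)
}
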
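# ---- profile extraction -----------------------------------------------------

#' Radial intensity profile along one axis
#'
#' Average unmasked intensity per unit radius step within a band of width
#' \code{width} px centered on the horizontal or vertical axis through the
#' beam center; the two antipodal rays are averaged into one curve. Radii
#' run from the crop floor to the inscribed-disk edge; steps whose band
#' contains no valid pixel are dropped. The profile encodes the real-space
#' periodicities of the keratin structure (distances in the molecular
#' package).
#'
#' @param pimg A \code{preprocessed_image}.
#' @param axis \code{"horizontal"} or \code{"vertical"}.
#' @param width Band width, px.
#' @return A \code{"profile_curve"}: \code{data.frame(x, y)} with attributes
#'   \code{kind}, \code{source}, \code{L}.
#' @export
extract_radial_profile <- function(pimg, axis = c("horizontal", "vertical"),
                                   width = 5) {
  axis <- match.arg(axis)
  stopifnot(inherits(pimg, "preprocessed_image"))
  g <- pixel_grid(dim(pimg$intensity), pimg$center_px)
  band <- if (axis == "horizontal") abs(g$dy) <= width / 2
          else abs(g$dx) <= width / 2
  sel <- band & pimg$valid
  if (!any(sel)) stop("radial profile: no valid pixels in the ", axis, " band")
  bins <- floor(g$r[sel])
  s <- rowsum(pimg$intensity[sel], bins)
  n <- rowsum(rep(1, sum(sel)), bins)
  x <- as.numeric(rownames(s))
  o <- order(x)
  new_profile(x[o], as.vector(s / n)[o], kind = "radial", source = axis)
}

#' Circular (azimuthal) intensity profile at one keratin arc
#'
#' Average unmasked intensity per 1-degree angular step over the annulus of
#' width \code{width} px at the radius of the d = 0.51 nm or d = 0.98 nm
#' period. Fiber symmetry makes the two half-circles redundant, so antipodal
#' angles are folded onto the semicircle [0, 180). The profile encodes the
#' orientation order of the structural units.
#'
#' @param pimg A \code{preprocessed_image}.
#' @param d_nm Arc period: 0.51 or 0.98.
#' @param width Annulus width, px.
#' @return A \code{"profile_curve"} with \code{L = 180} (periodic).
#' @export
extract_circular_profile <- function(pimg, d_nm, width = 5) {
  stopifnot(inherits(pimg, "preprocessed_image"), d_nm %in% c(0.51, 0.98))
  r0 <- d_to_radius(d_nm, pimg$geom)
  g <- pixel_grid(dim(pimg$intensity), pimg$center_px)
  sel <- abs(g$r - r0) <= width / 2 & pimg$valid
  if (!any(sel)) stop(sprintf("circular profile: annulus at d = %.2f nm fully masked", d_nm))
  bins <- floor(g$theta[sel] %% 180)
  s <- rowsum(pimg$intensity[sel], bins)
  n <- rowsum(rep(1, sum(sel)), bins)
  x <- as.numeric(rownames(s))
  o <- order(x)
  new_profile(x[o], as.vector(s / n)[o], kind = "circular",
              source = sprintf("circ_%03d", round(d_nm * 100)), L = 180,
              periodic = TRUE)
}

new_profile <- function(x, y, kind, source, L = NULL, periodic = FALSE) {
  stopifnot(all(diff(x) > 0), all(y >= 0))
  structure(data.frame(x = x, y = y),
            kind = kind, source = source,
            L = if (is.null(L)) max(x) - min(x) else L,
            periodic = periodic,
            class = c("profile_curve", "data.frame"))
}

# ---- Fourier series ---------------------------------------------------------

#' Fourier-series coefficients of a sampled profile
#'
#' Coefficients of the order-N Fourier expansion
#' \deqn{S_N(x) = a_0/2 + \sum_{n=1}^N a_n \cos(2\pi n x / L) +
#'   b_n \sin(2\pi n x / L)}
#' with \eqn{L} the x-range of the profile, evaluated by trapezoidal
#' quadrature on the sampled grid:
#' \eqn{a_n = (2/L)\int S(x) \cos(2\pi n x/L)\,dx} and likewise with sine
#' for \eqn{b_n}. The phase origin is the first sample of the curve. For
#' periodic (circular) profiles the wrap point is appended before
#' integration.
#'
#' @param curve A \code{profile_curve}, or \code{data.frame(x, y)}.
#' @param N Series order (default 10).
#' @param L Override for the x-range; defaults to the curve's own.
#' @return List with \code{a0}, \code{a} (length N), \code{b} (length N),
#'   \code{L}.
#' @export
fourier_coefficients <- function(curve, N = 10, L = NULL) {
  x <- curve$x; y <- curve$y
  stopifnot(length(x) == length(y), all(diff(x) > 0), N >= 1)
  if (N >= (length(x) - 1) / 2)
    stop(sprintf("aliasing: order N = %d needs more than %d sample points",
                 N, 2 * N + 1))
  if (is.null(L)) L <- attr(curve, "L")
  if (is.null(L)) L <- max(x) - min(x)
  t <- x - x[1]
  if (isTRUE(attr(curve, "periodic")) && max(t) < L) {
    t <- c(t, L); y <- c(y, y[1])
  }
  trapz <- function(f) sum(diff(t) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  a <- vapply(seq_len(N), function(n) 2 / L * trapz(y * cos(2 * pi * n * t / L)),
              numeric(1))
  b <- vapply(seq_len(N), function(n) 2 / L * trapz(y * sin(2 * pi * n * t / L)),
              numeric(1))
  list(a0 = 2 / L * trapz(y), a = a, b = b, L = L)
}

#' Reconstruct a profile from its Fourier coefficients
#'
#' @param coef Result of \code{\link{fourier_coefficients}}.
#' @param x Coordinates at which to evaluate (same origin as the fitted
#'   curve's first sample).
#' @param x0 Phase origin (first sample of the original curve).
#' @return Numeric vector \eqn{S_N(x)}.
#' @export
fourier_reconstruct <- function(coef, x, x0 = 0) {
  t <- x - x0
  s <- rep(coef$a0 / 2, length(t))
  for (n in seq_along(coef$a))
    s <- s + coef$a[n] * cos(2 * pi * n * t / coef$L) +
             coef$b[n] * sin(2 * pi * n * t / coef$L)
  s
}

# ---- feature vectors --------------------------------------------------------

curve_order <- c("rad_h", "rad_v", "circ_098", "circ_051")

#' Canonical feature names
#'
#' Fixed, documented ordering so feature tables reproduce bit-for-bit:
#' for each curve in order \code{rad_h, rad_v, circ_098, circ_051}, the
#' coefficients \code{a01..aN} then \code{b01..bN}.
#'
#' @param features \code{"radial"}, \code{"circular"} or \code{"both"}.
#' @param order Series order N.
#' @return Character vector of feature names (length 4N, 4N, or 8N).
#' @export
feature_names <- function(features = c("both", "radial", "circular"),
                          order = 10) {
  features <- match.arg(features)
  curves <- switch(features,
                   radial = curve_order[1:2],
                   circular = curve_order[3:4],
                   both = curve_order)
  unlist(lapply(curves, function(cv)
    c(sprintf("%s_a%02d", cv, seq_len(order)),
      sprintf("%s_b%02d", cv, seq_len(order)))))
}

#' Fourier feature vector of one preprocessed frame
#'
#' Extracts the two radial profiles (horizontal, vertical) and the two
#' circular profiles (d = 0.98 nm and d = 0.51 nm annuli) and concatenates
#' their Fourier coefficients \code{a_1..a_N, b_1..b_N}: 40 radial features,
#' 40 circular features, 80 for both, at the default N = 10. The constant
#' term a_0 is excluded by default — total intensity is standardized to a
#' constant, which makes it nearly degenerate (set \code{include_a0} to keep
#' it).
#'
#' @param pimg A \code{preprocessed_image}.
#' @param features Feature group: \code{"radial"}, \code{"circular"},
#'   \code{"both"}.
#' @param order Series order N (default 10).
#' @param radial_width,circular_width Averaging band/annulus widths, px.
#' @param include_a0 Keep the constant term of each curve as an extra
#'   feature.
#' @return Named numeric vector in canonical order.
#' @export
build_feature_vector <- function(pimg, features = c("both", "radial", "circular"),
                                 order = 10, radial_width = 5,
                                 circular_width = 5, include_a0 = FALSE) {
  features <- match.arg(features)
  curves <- switch(features,
                   radial = curve_order[1:2],
                   circular = curve_order[3:4],
                   both = curve_order)
  out <- numeric(0)
  for (cv in curves) {
    curve <- switch(cv,
      rad_h = extract_radial_profile(pimg, "horizontal", width = radial_width),
      rad_v = extract_radial_profile(pimg, "vertical", width = radial_width),
      circ_098 = extract_circular_profile(pimg, 0.98, width = circular_width),
      circ_051 = extract_circular_profile(pimg, 0.51, width = circular_width))
    cf <- fourier_coefficients(curve, N = order)
    v <- c(cf$a, cf$b)
    names(v) <- c(sprintf("%s_a%02d", cv, seq_len(order)),
                  sprintf("%s_b%02d", cv, seq_len(order)))
    if (include_a0) {
      v <- c(stats::setNames(cf$a0, sprintf("%s_a00", cv)), v)
    }
    out <- c(out, v)
  }
  if (!all(is.finite(out))) stop("non-finite Fourier features for sample ",
                                 pimg$sample_id)
  out
}

#' Feature table for a set of preprocessed frames
#'
#' @param pimgs List of \code{preprocessed_image}.
#' @param ... Passed to \code{\link{build_feature_vector}}.
#' @return Data frame: \code{sample_id, patient_id, label} plus one column
#'   per feature in canonical order.
#' @export
extract_features <- function(pimgs, ...) {
  rows <- lapply(pimgs, function(p) {
    fv <- build_feature_vector(p, ...)
    cbind(data.frame(sample_id = p$sample_id, patient_id = p$patient_id,
                     label = p$label, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
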
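test_that("radial profiles find the keratin periodicities where geometry predicts", {
  p <- fix_preprocessed(orientation = 37, seed = 42)
  vert <- extract_radial_profile(p, "vertical")
  r98 <- d_to_radius(0.98, p$geom); r51 <- d_to_radius(0.51, p$geom)
  near <- function(prof, r0, w = 6) prof$x[abs(prof$x - r0) <= w]
  peak_near <- function(prof, r0, w = 6) {
    sel <- abs(prof$x - r0) <= w
    prof$x[sel][which.max(prof$y[sel])]
  }
  expect_lt(abs(peak_near(vert, r98) - r98), 2)
  expect_lt(abs(peak_near(vert, r51) - r51), 2)
  # curves are long enough for an order-10 expansion
  expect_gte(nrow(vert), 42)
})

test_that("isotropic frames give matching radial axes and a flat circular profile", {
  iso <- suppressWarnings(preprocess_image(fix_isotropic(), fix_geom()))
  h <- extract_radial_profile(iso, "horizontal")
  v <- extract_radial_profile(iso, "vertical")
  common <- intersect(h$x, v$x)
  rel <- abs(h$y[match(common, h$x)] - v$y[match(common, v$x)]) /
    (h$y[match(common, h$x)] + 1)
  expect_lt(median(rel), 0.1)
  circ <- extract_circular_profile(iso, 0.98)
  expect_lt(stats::sd(circ$y) / mean(circ$y), 0.1)
})

test_that("aligned circular profile at 0.98 nm peaks on the vertical axis", {
  p <- fix_preprocessed(orientation = 37, seed = 42)
  circ <- extract_circular_profile(p, 0.98)
  expect_equal(attr(circ, "L"), 180)
  expect_lt(abs(circ$x[which.max(circ$y)] - 90), 3)
  # widening the annulus changes the profile of a radially smooth image
  # by under 2% RMS (narrow arcs mix in background contrast instead)
  s_sm <- structure_model(arc_radial_sigma = c(15, 15), hot_pixel_rate = 0,
                          dead_pixel_rate = 0)
  e <- pattern_expectation(s_sm, fix_geom(), 37, total_counts = 5e6)
  p_sm <- suppressWarnings(preprocess_image(new_raw_image_for_test(round(e)),
                                            fix_geom()))
  c5 <- extract_circular_profile(p_sm, 0.98, width = 5)
  c10 <- extract_circular_profile(p_sm, 0.98, width = 10)
  common <- intersect(c5$x, c10$x)
  rms <- sqrt(mean((c5$y[match(common, c5$x)] -
                    c10$y[match(common, c10$x)])^2))
  expect_lt(rms / mean(c5$y), 0.02)
})

test_that("Fourier coefficients recover pure harmonics and constants", {
  L <- 180
  x <- seq(0, L, length.out = 721)
  cst <- data.frame(x = x, y = rep(3.5, length(x)))
  cf <- fourier_coefficients(cst, N = 10, L = L)
  expect_equal(cf$a0, 2 * 3.5, tolerance = 1e-12)
  expect_lt(max(abs(c(cf$a, cf$b))), 1e-12)
  harm <- data.frame(x = x, y = cos(2 * pi * 3 * x / L))
  cf3 <- fourier_coefficients(harm, N = 10, L = L)
  expect_equal(cf3$a[3], 1, tolerance = 1e-3)
  expect_lt(max(abs(c(cf3$a[-3], cf3$b))), 1e-3)
  sh <- data.frame(x = x, y = sin(2 * pi * 5 * x / L))
  cf5 <- fourier_coefficients(sh, N = 10, L = L)
  expect_equal(cf5$b[5], 1, tolerance = 1e-3)
})

test_that("coefficients match a 100x-resolution quadrature oracle to 4 significant figures", {
  set.seed(7)
  trapz <- function(t, f) sum(diff(t) * (head(f, -1) + tail(f, -1)) / 2)
  for (rep in 1:3) {
    # random smooth curve: low-order Fourier mixture plus a smooth envelope
    L <- 109
    amp <- rnorm(6); phs <- runif(6, 0, 2 * pi)
    fun <- function(x) 5 + exp(-x / L) +
      colSums(amp * sin(outer(1:6, 2 * pi * x / L) + phs))
    x <- seq(0, L, by = 0.25)
    cf <- fourier_coefficients(data.frame(x = x, y = fun(x)), N = 10, L = L)
    # oracle: dense quadrature of the underlying curve at 100x resolution
    xf <- seq(0, L, by = 0.25 / 100)
    yf <- fun(xf)
    for (n in c(1, 4, 10)) {
      a_or <- 2 / L * trapz(xf, yf * cos(2 * pi * n * xf / L))
      b_or <- 2 / L * trapz(xf, yf * sin(2 * pi * n * xf / L))
      scale <- max(1, abs(a_or), abs(b_or))
      expect_lt(abs(cf$a[n] - a_or) / scale, 1e-4)
      expect_lt(abs(cf$b[n] - b_or) / scale, 1e-4)
    }
  }
})

test_that("aliasing guard rejects orders the sampling cannot support", {
  x <- 0:20
  expect_error(fourier_coefficients(data.frame(x = x, y = x * 0 + 1), N = 10),
               "aliasing")
})

test_that("truncated reconstruction error decreases monotonically in N", {
  p <- fix_preprocessed(orientation = 37, seed = 42)
  prof <- extract_radial_profile(p, "vertical")
  L <- attr(prof, "L")
  rmse <- vapply(c(2, 5, 10, 15), function(N) {
    cf <- fourier_coefficients(prof, N = N)
    sqrt(mean((fourier_reconstruct(cf, prof$x, x0 = prof$x[1]) - prof$y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 1e-9))
  # energy of the truncation never exceeds the curve's energy
  cf <- fourier_coefficients(prof, N = 10)
  t <- prof$x - prof$x[1]
  recon <- fourier_reconstruct(cf, prof$x, x0 = prof$x[1])
  expect_lte(mean((recon - mean(prof$y))^2), var(prof$y) * 1.02)
})

test_that("feature vectors have the contracted dimension and canonical names", {
  p <- fix_preprocessed()
  radial <- build_feature_vector(p, features = "radial")
  circular <- build_feature_vector(p, features = "circular")
  both <- build_feature_vector(p, features = "both")
  expect_length(radial, 40)
  expect_length(circular, 40)
  expect_length(both, 80)
  expect_identical(names(both), feature_names("both", 10))
  expect_identical(names(both)[1:20],
                   c(sprintf("rad_h_a%02d", 1:10), sprintf("rad_h_b%02d", 1:10)))
  expect_true(all(is.finite(both)))
  # a_0 excluded by default, included on request
  with_a0 <- build_feature_vector(p, features = "radial", include_a0 = TRUE)
  expect_length(with_a0, 42)
})

test_that("features are invariant to stored orientation and translation (CR invariance)", {
  f1 <- build_feature_vector(fix_preprocessed(orientation = 20, seed = 7))
  f2 <- build_feature_vector(fix_preprocessed(orientation = 110, seed = 8))
  g2 <- detector_geometry(center_px = c(130.5, 125.5))
  img3 <- render_pattern(fix_structure(), g2, 75, seed = 9,
                         total_counts = 5e6)
  f3 <- build_feature_vector(suppressWarnings(preprocess_image(img3, g2)))
  fc <- build_feature_vector(fix_preprocessed(orientation = 50, seed = 10,
                                              class = "cancer"))
  within <- max(sqrt(sum((f1 - f2)^2)), sqrt(sum((f1 - f3)^2)))
  between <- sqrt(sum((f1 - fc)^2))
  expect_lt(within, 0.2 * between)
})
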
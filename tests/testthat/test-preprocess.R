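test_that("beam center is recovered within half a pixel and is translation-equivariant", {
  img <- fix_pattern()
  c0 <- find_center(img$counts)
  expect_lt(max(abs(c0 - c(127.5, 127.5))), 0.5)
  # render the same pattern with the beam displaced by (+3, -2) px
  g2 <- detector_geometry(center_px = c(127.5 + 3, 127.5 - 2))
  img2 <- render_pattern(fix_structure(), g2, 37, seed = 42,
                         total_counts = 5e6)
  c2 <- find_center(img2$counts)
  expect_lt(max(abs((c2 - c0) - c(3, -2))), 0.5)
})

test_that("a symmetric noiseless pattern centers exactly", {
  e <- pattern_expectation(fix_structure(), fix_geom(), 90,
                           total_counts = 1e6)
  c0 <- find_center(round(e))
  expect_lt(max(abs(c0 - c(127.5, 127.5))), 0.05)
})

test_that("centering fails loudly when no central intensity exists", {
  m <- matrix(0, 256, 256)
  m[10, 10] <- 1000  # bright corner, empty middle
  expect_error(find_center(m), "centering failure")
})

test_that("AgBH calibration measures the q-scale and respects its tolerance", {
  geom <- fix_geom()
  cal <- calibrate_scale(render_agbh(geom, seed = 5), geom)
  expect_lt(abs(cal$scale_factor - 1), 0.005)
  expect_false(cal$applied)   # spread within 3%: leave the data alone
  # detector 5% too far: measured radius inflates, factor ~ 1/1.05
  far <- detector_geometry(distance_mm = geom$distance_mm * 1.05)
  cal2 <- calibrate_scale(render_agbh(far, seed = 6), geom)
  expect_true(cal2$applied)
  expect_equal(cal2$scale_factor, 1 / 1.05, tolerance = 0.01)
  # featureless frame: no detectable ring
  flat <- new_flat <- matrix(rpois(256 * 256, 5), 256, 256)
  flat[120:136, 120:136] <- 500  # a beam spot so centering succeeds
  expect_error(calibrate_scale(flat, geom), "no detectable AgBH ring")
})

test_that("hot-pixel repair: constant annulus, no-op, and >= 99% detection", {
  geom <- fix_geom()
  # constant-value annuli: an injected 1e6 spike becomes exactly c
  g_r <- sqrt(outer((0:255 - 127.5)^2, (0:255 - 127.5)^2, "+"))
  m <- matrix(20, 256, 256)
  hit <- which(floor(g_r) == 60)[17]
  m[hit] <- 1e6
  rr <- suppressWarnings(remove_hot_pixels(m, c(127.5, 127.5)))
  expect_equal(rr$counts[hit], 20)
  expect_true(rr$repaired[hit])
  expect_equal(sum(rr$repaired), 1)
  # defect-free frame: repair is an exact no-op
  clean <- fix_pattern(seed = 3)
  rr0 <- suppressWarnings(remove_hot_pixels(clean$counts,
                                            find_center(clean$counts)))
  expect_equal(sum(rr0$repaired), 0)
  expect_equal(rr0$counts, clean$counts + 0)
  # simulator ground truth: detection rate of injected hot pixels
  s <- fix_structure(clean = FALSE)
  s$hot_pixel_rate <- 5e-3  # ~330 injected spikes for a tight rate estimate
  injected <- 0; found <- 0
  for (sd in 1:3) {
    img <- render_pattern(s, geom, 40, seed = sd, total_counts = 5e6)
    rr <- suppressWarnings(remove_hot_pixels(img$counts,
                                             find_center(img$counts)))
    injected <- injected + length(img$hot_idx)
    found <- found + sum(img$hot_idx %in% which(rr$repaired))
  }
  expect_gte(found / injected, 0.99)
})

test_that("crop masks the spot, the corners, and keeps the arcs", {
  geom <- fix_geom()
  mask <- crop_mask(geom$shape, c(127.5, 127.5), geom)
  r19 <- q_to_radius(1.9, geom)    # below the q floor
  px <- c(128, 128 + round(r19))   # on the horizontal axis
  expect_false(mask[px[1], px[2]])
  r_arc <- d_to_radius(0.98, geom) # the 0.98 nm arc: retained
  expect_true(mask[128, 128 + round(r_arc)])
  expect_false(mask[1, 1])         # corner: circular crop
})

test_that("rotation alignment brings the fiber axis to vertical", {
  p <- fix_preprocessed(orientation = 37, seed = 42)
  ori <- pattern_orientation(p$intensity, p$center_px, p$geom,
                             valid = p$valid)
  expect_false(ori$isotropic)
  expect_lt(abs(ori$orientation_deg - 90), 2)
  expect_equal(p$rotation_deg, 90 - 37, tolerance = 2)
  # two orientations of the same structure agree pixelwise after alignment
  p2 <- fix_preprocessed(orientation = 127, seed = 43)
  v <- p$valid & p2$valid
  expect_gte(cor(p$intensity[v], p2$intensity[v]), 0.98)
  # isotropic pattern: declared convention rotation = 0, flagged
  iso <- suppressWarnings(preprocess_image(fix_isotropic(), fix_geom()))
  expect_identical(iso$rotation_deg, 0)
  expect_true(iso$flags$isotropic)
})

test_that("standardization fixes the unmasked total at 5 mln and preserves ratios", {
  for (tc in c(2.5e6, 5e6, 9e6)) {
    p <- fix_preprocessed(orientation = 80, seed = 21, total_counts = tc)
    expect_equal(sum(p$intensity[p$valid]), 5e6, tolerance = 5 / 5e6)
  }
  # conservation: standardization is one scalar, so pairwise intensity
  # ratios survive it exactly
  p <- fix_preprocessed(orientation = 80, seed = 21, total_counts = 2.5e6)
  pre <- p$intensity / p$standardize_scalar
  i <- which(p$valid & p$intensity > 0)[c(10, 500)]
  expect_equal(p$intensity[i[1]] / p$intensity[i[2]], pre[i[1]] / pre[i[2]])
  expect_true(all(p$intensity[!p$valid] == 0))
  expect_error(
    preprocess_image(new_raw_image_for_test(matrix(0L, 256, 256))),
    "centering|zero total")
})

test_that("preprocessing an aligned image again is near-idempotent", {
  p <- fix_preprocessed(orientation = 37, seed = 42)
  c1 <- find_center(round(p$intensity))
  expect_lt(max(abs(c1 - p$center_px)), 0.5)
  ori <- pattern_orientation(p$intensity, p$center_px, p$geom,
                             valid = p$valid)
  expect_lt(abs(ori$orientation_deg - 90), 1)  # re-rotation would be ~0
})

test_that("masked pixels never reach a profile", {
  p <- fix_preprocessed()
  prof <- extract_radial_profile(p, "horizontal")
  r_min <- q_to_radius(2, p$geom)
  expect_true(all(prof$x >= floor(r_min)))
  expect_true(all(prof$x <= 127.5))
})
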
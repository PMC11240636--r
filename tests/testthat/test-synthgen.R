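test_that("rendering is deterministic and degenerates to an empty frame", {
  geom <- fix_geom()
  s <- fix_structure()
  a <- render_pattern(s, geom, 30, seed = 9)
  b <- render_pattern(s, geom, 30, seed = 9)
  expect_identical(a$counts, b$counts)
  z <- structure_model(arc_amplitude = c(0, 0), background_level = 0,
                       beam_amplitude = 0, hot_pixel_rate = 0,
                       dead_pixel_rate = 0)
  img <- render_pattern(z, geom, 0, seed = 1, total_counts = 1)
  expect_true(all(img$counts == 0))
})

test_that("counts are non-negative integers at the detector shape", {
  img <- fix_pattern()
  expect_identical(dim(img$counts), fix_geom()$shape)
  expect_true(all(img$counts >= 0))
  expect_true(all(img$counts == round(img$counts)))
})

test_that("Monte-Carlo mean matches the closed-form expected surface", {
  geom <- fix_geom()
  s <- fix_structure()
  e <- pattern_expectation(s, geom, 30, total_counts = 4e6)
  acc <- matrix(0, geom$shape[1], geom$shape[2])
  n_rep <- 200
  for (i in seq_len(n_rep))
    acc <- acc + render_pattern(s, geom, 30, seed = i,
                                total_counts = 4e6)$counts
  g_ann <- floor(sqrt(outer((0:255 - 127.5)^2, (0:255 - 127.5)^2, "+")))
  obs <- rowsum(as.vector(acc / n_rep), as.vector(g_ann))
  expe <- rowsum(as.vector(e), as.vector(g_ann))
  se <- sqrt(expe / n_rep)
  keep <- expe > 100  # annuli carrying real signal
  expect_lt(max(abs((obs - expe) / se)[keep]), 3)
})

test_that("AgBH rings: fundamental below the window, radii increase, deterministic", {
  geom <- fix_geom()
  rings <- agbh_ring_radii(geom)
  expect_lt(rings$q_nm[1], 2)        # first visible ring inside the window
  expect_gt(rings$q_nm[2], 2)        # is a harmonic of d(001)
  expect_equal(rings$q_nm, 2 * pi / rings$d_nm)
  expect_true(all(diff(rings$r_px) > 0))
  expect_identical(render_agbh(geom, seed = 3)$counts,
                   render_agbh(geom, seed = 3)$counts)
})

test_that("cohort planning honors prevalence, patient-level labels and seeds", {
  spec <- cohort_spec(n_patients = 265, cancer_prevalence = 104 / 265,
                      seed = 123)
  plan <- plan_cohort(spec)
  m <- plan$manifest
  pat <- unique(m[, c("patient_id", "label")])
  expect_equal(nrow(pat), 265)
  expect_equal(sum(pat$label == "cancer"), 104)
  expect_equal(sum(pat$label == "no_cancer"), 161)
  # one label per patient, >= 1 sample each
  expect_false(anyDuplicated(pat$patient_id) > 0)
  expect_true(all(table(m$patient_id) >= 1))
  # byte-identical manifests under a fixed seed
  plan2 <- plan_cohort(spec)
  expect_identical(m, plan2$manifest)
  # unaffected_sample_rate = 0: every cancer sample keeps the cancer structure
  plan0 <- plan_cohort(cohort_spec(n_patients = 40, seed = 5,
                                   unaffected_sample_rate = 0))
  expect_true(!any(plan0$manifest$unaffected))
  expect_error(cohort_spec(cancer_prevalence = 1.2), "prevalence")
})

test_that("rendered cohort samples carry their manifest identity", {
  plan <- plan_cohort(cohort_spec(n_patients = 4, seed = 2))
  img <- render_cohort_sample(plan, 3)
  expect_identical(img$sample_id, plan$manifest$sample_id[3])
  expect_identical(img$patient_id, plan$manifest$patient_id[3])
  expect_identical(img$label, plan$manifest$label[3])
})

test_that("cancer effect moves oriented amplitude down and ring share up at 0.98 nm", {
  st <- default_structures()
  i98 <- which(st$no_cancer$arc_d_nm == 0.98)
  i51 <- which(st$no_cancer$arc_d_nm == 0.51)
  expect_lt(st$cancer$arc_amplitude[i98], st$no_cancer$arc_amplitude[i98])
  expect_gt(st$cancer$ring_fraction[i98], st$no_cancer$ring_fraction[i98])
  # weaker same-direction effect at 0.51 nm
  d98 <- st$no_cancer$ring_fraction[i98] - st$cancer$ring_fraction[i98]
  d51 <- st$no_cancer$ring_fraction[i51] - st$cancer$ring_fraction[i51]
  expect_lt(abs(d51), abs(d98))
  # effect = 0 collapses the classes
  st0 <- default_structures(effect = 0)
  expect_equal(st0$cancer, st0$no_cancer)
})
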
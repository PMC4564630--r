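test_that("generator config validates its protocol parameters", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, bundles_per_layer = c(5, 2)))
  expect_error(generator_config(seed = 1, fbl_sigma_log = 0))
  expect_error(generator_config(seed = 1, posterior_absent_prob = 2))
  expect_error(generator_config(seed = 1, targets = data.frame(a = 1)),
               "targets")
  cfg <- generator_config(seed = 5)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$bundles_per_layer, c(10L, 60L))
  expect_equal(cfg$points_per_bundle, c(10L, 20L))
})

test_that("generation is deterministic in the seed and sub-streams", {
  cfg <- generator_config(seed = 9, bundles_per_layer = c(3, 5),
                          layers_per_part = 1)
  a <- generate_specimen("B", cfg, "B1")
  b <- generate_specimen("B", cfg, "B1")
  expect_identical(a$points, b$points)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$specimen, b$specimen)

  cfg2 <- generator_config(seed = 10, bundles_per_layer = c(3, 5),
                           layers_per_part = 1)
  c2 <- generate_specimen("B", cfg2, "B1")
  expect_false(identical(a$points, c2$points))

  # byte-identical CSV output for the same seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  readr::write_csv(a$points, f1)
  readr::write_csv(b$points, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("noiseless straight fibers measure exactly as configured", {
  cfg <- generator_config(seed = 13, digitization_noise_sd_cm = 0,
                          fiber_curvature = 0, bundles_per_layer = c(3, 4),
                          layers_per_part = 1)
  sp <- generate_specimen("A", cfg, "A1")
  m <- measure_bundles(sp$points)
  j <- dplyr::inner_join(m, sp$ground_truth,
                         by = c("specimen_id", "bundle_id", "region", "part",
                                "layer_depth_mm"))
  expect_gt(nrow(j), 10)
  expect_lt(max(abs(j$fbl_cm - j$true_fbl_cm)), 1e-6)
  expect_lt(max(abs(j$lat_pa_deg - j$true_lat_pa_deg)), 1e-3)
  expect_lt(max(abs(j$med_pa_deg - j$true_med_pa_deg)), 1e-3)
  # curvature 0 makes both ends share the lateral angle
  expect_lt(max(abs(j$true_lat_pa_deg - j$true_med_pa_deg)), 1e-12)
})

test_that("measured architecture tracks per-bundle ground truth under noise", {
  cfg <- generator_config(seed = 17, bundles_per_layer = c(6, 8),
                          layers_per_part = 1)
  sp <- generate_specimen("B", cfg, "B1")
  m <- measure_bundles(sp$points)
  j <- dplyr::inner_join(m, sp$ground_truth,
                         by = c("specimen_id", "bundle_id", "region", "part",
                                "layer_depth_mm"))
  expect_equal(nrow(j), nrow(sp$ground_truth))
  expect_lt(median(abs(j$fbl_cm / j$true_fbl_cm - 1)), 0.02)
  expect_lt(median(abs(j$lat_pa_deg - j$true_lat_pa_deg)), 3)
  expect_lt(median(abs(j$med_pa_deg - j$true_med_pa_deg)), 3)
  # arc length genuinely exceeds the chord for curved fibers
  expect_gt(median(j$fbl_cm /
                     sqrt((tapply(sp$points$x_cm[sp$points$record_type == "fiber"],
                                  sp$points$record_id[sp$points$record_type == "fiber"],
                                  function(v) diff(range(v))))[j$bundle_id]^2)),
            1)
})

test_that("generated specimens satisfy the specimen-model invariants", {
  cfg <- generator_config(seed = 19, bundles_per_layer = c(3, 5),
                          layers_per_part = 1)
  for (cat in c("A", "B", "C")) {
    sp <- generate_specimen(cat, cfg, paste0(cat, "1"))
    expect_silent(validate_digitized_points(sp$points))
    expect_equal(
      classify_tear(sp$specimen$thickness,
                    sp$specimen$spans_full_sagittal_width),
      cat
    )
    if (cat == "A") {
      expect_true(is.na(sp$specimen$coronal_cm))
      expect_false("tear_boundary" %in% sp$points$record_type)
    } else {
      expect_gt(sp$specimen$coronal_cm, 0)
      # re-measuring the emitted tear boundary in the landmark frame
      # recovers the recorded diameters
      fr <- build_specimen_frame(
        c(sp$specimen$lm_ss_x, sp$specimen$lm_ss_y, sp$specimen$lm_ss_z),
        c(sp$specimen$lm_cp_x, sp$specimen$lm_cp_y, sp$specimen$lm_cp_z),
        c(sp$specimen$lm_gt_x, sp$specimen$lm_gt_y, sp$specimen$lm_gt_z)
      )
      tb <- sp$points[sp$points$record_type == "tear_boundary", ]
      d <- measure_tear_dimensions(tb, fr)
      expect_equal(d$coronal_cm, sp$specimen$coronal_cm, tolerance = 1e-6)
      expect_equal(d$sagittal_cm, sp$specimen$sagittal_cm, tolerance = 1e-6)
    }
    # bundle point counts within the digitization protocol
    counts <- dplyr::count(
      dplyr::filter(sp$points, record_type == "fiber"), record_id
    )
    expect_true(all(counts$n >= 10 & counts$n <= 20))
  }
})

test_that("posterior-region absence is honored and drawn per specimen", {
  cfg <- generator_config(seed = 23, bundles_per_layer = c(3, 4),
                          layers_per_part = 1, posterior_absent_prob = 1)
  sp <- generate_specimen("C", cfg, "C1")
  expect_false(sp$specimen$posterior_present)
  expect_false("posterior" %in% sp$points$region[sp$points$record_type == "fiber"])
  pres <- posterior_region_present(sp$points)
  expect_false(pres$posterior_present)

  # forced override
  sp2 <- generate_specimen("C", cfg, "C2", posterior_absent = FALSE)
  expect_true(sp2$specimen$posterior_present)

  # non-C categories always keep the posterior region
  spA <- generate_specimen("A", cfg, "A1")
  expect_true(spA$specimen$posterior_present)
})

test_that("cohorts have the study design and independent specimen streams", {
  cfg <- generator_config(seed = 29, bundles_per_layer = c(3, 4),
                          layers_per_part = 1)
  coh <- generate_cohort(cfg, n_per_category = 1)
  expect_s3_class(coh, "fascicle_cohort")
  expect_equal(nrow(coh$specimens), 3)
  expect_equal(sort(coh$specimens$category), c("A", "B", "C"))

  coh4 <- generate_cohort(cfg, n_per_category = 2)
  expect_equal(nrow(coh4$specimens), 6)
  # growing the cohort does not perturb the shared specimens
  p1 <- coh$points[coh$points$specimen_id == "A1", ]
  p2 <- coh4$points[coh4$points$specimen_id == "A1", ]
  expect_identical(p1, p2)
})

test_that("a default cohort recovers the per-part configured medians", {
  coh <- generate_cohort(generator_config(seed = 42), n_per_category = 4)
  m <- measure_bundles(coh$points) |>
    dplyr::left_join(coh$specimens[, c("specimen_id", "category")],
                     by = "specimen_id")
  s <- summarize_architecture(m)
  j <- dplyr::left_join(s, default_architecture_targets(),
                        by = c("region", "part", "category"))
  j <- j[j$n_bundles >= 200, ]
  expect_gte(nrow(j), 15)
  expect_lt(max(abs(j$fbl_cm_median - j$fbl_cm) / j$fbl_cm), 0.05)
  expect_lt(max(abs(j$lat_pa_deg_median - j$lat_pa_deg)), 2)
  expect_lt(max(abs(j$med_pa_deg_median - j$med_pa_deg)), 2)
  # qualitative structure survives measurement: anterior fibers shorten and
  # steepen with tear severity in every part
  ant <- j[j$region == "anterior", ]
  for (p in unique(ant$part)) {
    cell <- ant[ant$part == p, ]
    cell <- cell[order(cell$category), ]
    expect_true(all(diff(cell$fbl_cm_median) < 0))
    expect_gt(cell$lat_pa_deg_median[3], max(cell$lat_pa_deg_median[1:2]))
  }
})

test_that("fiber length measurement tolerates coarse digitization noise", {
  tgt <- default_architecture_targets()
  tgt$fbl_cm <- 5
  cfg <- generator_config(seed = 47, targets = tgt,
                          digitization_noise_sd_cm = 0.05,
                          fbl_sigma_log = 0.01,
                          bundles_per_layer = c(8, 10), layers_per_part = 1)
  sp <- generate_specimen("B", cfg, "B1")
  m <- measure_bundles(sp$points)
  j <- dplyr::inner_join(m, sp$ground_truth,
                         by = c("specimen_id", "bundle_id", "region", "part",
                                "layer_depth_mm"))
  # an interpolating spline cannot beat the chord-summation noise floor of
  # about 2*sigma^2/h^2 (~2.5% at 0.05 cm noise and ~0.45 cm site spacing);
  # the measured median error sits just above that floor, and well under 1%
  # at the default 0.02 cm digitizer noise (checked above)
  expect_lt(median(abs(j$fbl_cm / j$true_fbl_cm - 1)), 0.04)
})
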
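rois_no_ref <- function(nx = 128, ny = 128) {
  roi_set(roi_rect("P1", "photoconverted", 0.1 * nx, 0.1 * ny, 0.35 * nx, 0.35 * ny),
          roi_rect("C1", "control", 0.6 * nx, 0.6 * ny, 0.3 * nx, 0.3 * ny),
          roi_rect("bg", "background", 0.75 * nx, 0.05 * ny, 0.2 * nx, 0.12 * ny))
}

test_that("scene generation is bit-reproducible under a fixed seed", {
  s1 <- quick_scene(seed = 7, n_timepoints = 2,
                    optics = optics_model(gaussian_sd = 2, poisson_gain = 0.5))
  s2 <- quick_scene(seed = 7, n_timepoints = 2,
                    optics = optics_model(gaussian_sd = 2, poisson_gain = 0.5))
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$truth$cells, s2$truth$cells)
  s3 <- quick_scene(seed = 8, n_timepoints = 2,
                    optics = optics_model(gaussian_sd = 2, poisson_gain = 0.5))
  expect_false(identical(s1$stack$pixels, s3$stack$pixels))
})

test_that("zero hazard gives zero recombined cells at all timepoints", {
  cfg <- scene_config("culture2d", field_size_um = c(256, 256), pixel_size_um = 2,
                      n_timepoints = 3, frame_interval_h = 12, seed = 3)
  sim <- simulate_scene(cfg,
                        recombination_model(background_hazard_per_h = 0,
                                            light_hazard_multiplier = 1),
                        optics_noise_free(), rois = rois_no_ref(),
                        n_cells = 50)
  expect_true(all(is.infinite(sim$truth$cells$recomb_time_h)))
  # no reporter fluorophore anywhere in the clean channels
  ch <- match(c("mCFP", "nGFP", "cYFP", "cRFP"), sim$truth$channel_names)
  expect_equal(sum(sim$truth$clean[, ch, , , ]), 0)
})

test_that("without leak-through and noise the cYFP channel is its clean map plus offset", {
  sim <- quick_scene(seed = 5, n_timepoints = 2, lf = 0, offset = 7, n_cells = 50)
  ich <- match("cYFP", sim$stack$channel_names)
  expect_equal(sim$stack$pixels[, ich, , , ],
               sim$truth$clean[, ich, , , ] + 7, tolerance = 1e-12)
  # and with leak-through on, the recorded cYFP equals clean + LF * nGFP + offset
  sim2 <- quick_scene(seed = 5, n_timepoints = 2, lf = 0.3, offset = 7, n_cells = 50)
  ig <- match("nGFP", sim2$stack$channel_names)
  expect_equal(sim2$stack$pixels[, ich, , , ],
               sim2$truth$clean[, ich, , , ] +
                 0.3 * sim2$truth$clean[, ig, , , ] + 7,
               tolerance = 1e-12)
})

test_that("recombined fraction follows the configured hazard closed form", {
  # single scene: fraction of illuminated cells recombined by 24 h inside
  # the 99% binomial envelope of 1 - exp(-24 * 0.05 * 20)
  cfg <- scene_config("culture2d", field_size_um = c(256, 256), pixel_size_um = 2,
                      n_timepoints = 2, frame_interval_h = 24, seed = 11)
  sim <- simulate_scene(cfg,
                        recombination_model(background_hazard_per_h = 0.05,
                                            light_hazard_multiplier = 20),
                        optics_noise_free(), rois = rois_no_ref(),
                        n_cells = 120, cell_radius_um = 6)
  cells <- sim$truth$cells
  inroi <- cells$inside_photoconverted
  p_true <- 1 - exp(-24 * 0.05 * 20)
  n <- sum(inroi)
  f <- mean(cells$recomb_time_h[inroi] <= 24)
  half <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / n)
  expect_gte(f, p_true - half - 1e-12)
  expect_lte(f, p_true + half + 1e-12)

  # across 100 replicate seeds (small scenes), the mean recombined count
  # matches the closed form within 3 standard errors
  p_bg <- 1 - exp(-12 * 0.02)
  fr <- vapply(1:100, function(s) {
    cfg <- scene_config("culture2d", field_size_um = c(128, 128), pixel_size_um = 2,
                        n_timepoints = 1, frame_interval_h = 12, seed = 1000 + s)
    sm <- simulate_scene(cfg,
                         recombination_model(background_hazard_per_h = 0.02,
                                             light_hazard_multiplier = 1),
                         optics_noise_free(),
                         rois = rois_no_ref(64, 64), n_cells = 20,
                         store_clean = FALSE)
    mean(sm$truth$cells$recomb_time_h <= 12)
  }, 0)
  se <- sqrt(p_bg * (1 - p_bg) / (100 * 20))
  expect_lt(abs(mean(fr) - p_bg), 3 * se)
})

test_that("noise-free fluorophore totals equal per-cell brightness times attenuation", {
  cfg <- scene_config("organoid", field_size_um = c(480, 480), pixel_size_um = 2,
                      n_z = 3, z_step_um = 5, n_timepoints = 2,
                      frame_interval_h = 20, seed = 9)
  sim <- simulate_scene(cfg, recombination_model(background_hazard_per_h = 0.05),
                        optics_noise_free(z_attenuation_per_um = 0.02),
                        n_cells = 120)
  cells <- sim$truth$cells
  ch <- match(c("mCFP", "nGFP", "cYFP", "cRFP"), sim$truth$channel_names)
  for (t in 1:2) {
    tt <- sim$stack$time_points_h[t]
    on <- cells$recomb_time_h <= tt
    expected <- sum(cells$brightness_total[on] * cells$z_attenuation[on])
    got <- sum(sim$truth$clean[t, ch, , , ])
    expect_lt(abs(got - expected) / max(expected, 1), 1e-9)
  }
})

test_that("scene preconditions are enforced", {
  cfg <- scene_config("culture2d", field_size_um = c(64, 64), pixel_size_um = 2,
                      n_timepoints = 1, frame_interval_h = 1, seed = 1)
  bad <- roi_set(roi_rect("P1", "photoconverted", 10, 10, 100, 100))
  expect_error(suppressWarnings(simulate_scene(cfg, recombination_model(),
                                               optics_noise_free(), rois = bad,
                                               n_cells = 5)),
               "outside")
  expect_error(recombination_model(outcome_probs = c(mCFP = 0.5, nGFP = 0.5,
                                                     cYFP = 0.2, cRFP = 0.2)),
               "sum to 1")
  expect_error(scene_config("culture2d", field_size_um = c(100.7, 100),
                            pixel_size_um = 2),
               "integer pixel dimensions")
  expect_error(simulate_scene(scene_config("skin_zstack"), recombination_model(),
                              optics_noise_free()),
               "skin")
})

test_that("skin relocation moves the eGFP depth centroid across the collagen band", {
  cfg <- scene_config("skin_zstack", field_size_um = c(96, 96), n_z = 12,
                      n_timepoints = 5, frame_interval_h = 48, seed = 21)
  sim <- simulate_skin_relocation(cfg, relocation_day = 5,
                                  optics = optics_noise_free(), n_cells = 15)
  shg_peak <- sim$truth$shg_peak_z
  egfp <- match("eGFP", sim$stack$channel_names)
  centroid_z <- function(t) {
    tz <- vapply(seq_len(12), function(z) sum(sim$stack$pixels[t, egfp, z, , ]), 0)
    sum(seq_len(12) * tz) / sum(tz)
  }
  # days 0,2,4 before relocation; 6,8 after
  expect_lt(centroid_z(2), shg_peak)  # day 2
  expect_lt(centroid_z(3), shg_peak)  # day 4
  expect_gt(centroid_z(4), shg_peak)  # day 6
  expect_gt(centroid_z(5), shg_peak)  # day 8
})

test_that("the collagen band is static and an out-of-span relocation warns", {
  cfg <- scene_config("skin_zstack", field_size_um = c(96, 96), n_z = 12,
                      n_timepoints = 3, frame_interval_h = 24, seed = 22)
  sim <- simulate_skin_relocation(cfg, relocation_day = Inf,
                                  optics = optics_noise_free(), n_cells = 10)
  shg <- match("SHG", sim$stack$channel_names)
  prof <- function(t) vapply(seq_len(12), function(z)
    sum(sim$stack$pixels[t, shg, z, , ]), 0)
  expect_equal(prof(1), prof(2))
  expect_equal(prof(1), prof(3))
  # static scene: eGFP centroid constant over time
  egfp <- match("eGFP", sim$stack$channel_names)
  cz <- vapply(1:3, function(t) {
    tz <- vapply(seq_len(12), function(z) sum(sim$stack$pixels[t, egfp, z, , ]), 0)
    sum(seq_len(12) * tz) / sum(tz)
  }, 0)
  expect_equal(cz[1], cz[2])
  expect_equal(cz[1], cz[3])
  expect_warning(
    simulate_skin_relocation(
      scene_config("skin_zstack", field_size_um = c(96, 96), n_z = 12,
                   n_timepoints = 3, frame_interval_h = 24, seed = 23),
      relocation_day = 50, optics = optics_noise_free(), n_cells = 5),
    "static")
})
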
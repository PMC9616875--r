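test_that("area-normalized intensity is a ratio identity and homogeneous", {
  a <- array(0, c(2, 1, 1, 10, 10))
  mask <- matrix(FALSE, 10, 10); mask[3:7, 3:7] <- TRUE
  a[1, 1, 1, , ][mask] <- 6.5
  a[2, 1, 1, , ][mask] <- 13
  s <- image_stack(a, channel_names = "GFP", pixel_size_um = 2)
  cv <- quantify_timelapse_2d(s, mask, "GFP")
  # uniform value v over the mask gives v per um^2 of... v / px_area
  expect_equal(cv$value, c(6.5, 13) / 4)
  expect_equal(cv$value[2], 2 * cv$value[1])  # doubling intensities doubles the curve
  expect_equal(unique(cv$normalizer_kind), "cell_area")
  # a zero-area mask flags and returns 0
  expect_warning(cv0 <- quantify_timelapse_2d(s, matrix(FALSE, 10, 10), "GFP"),
                 "zero-area")
  expect_equal(cv0$value, c(0, 0))
  expect_true(all(cv0$zero_area))
})

test_that("illuminated regions outrun controls in a 2D culture time-lapse", {
  sim <- quick_scene(seed = 51, n_timepoints = 4, frame_interval_h = 12,
                     offset = 5, n_cells = 60,
                     optics = optics_model(leakthrough_lf_true = 0.15,
                                           background_offset = 5,
                                           gaussian_sd = 1, poisson_gain = 0.5))
  bs <- subtract_background(sim$stack, sim$truth$rois)
  rois <- sim$truth$rois
  light_mask <- rasterize_roi(rois[["P1"]], sim$stack)
  ctrl_mask <- rasterize_roi(rois[["C1"]], sim$stack)
  tot_curve <- function(mask) {
    Reduce(`+`, lapply(c("mCFP", "nGFP", "cYFP", "cRFP"), function(fl)
      quantify_timelapse_2d(bs, mask, fl, mode = "roi")$value))
  }
  light <- tot_curve(light_mask); ctrl <- tot_curve(ctrl_mask)
  expect_true(all(light[-1] > ctrl[-1]))
})

test_that("organoid read-out integrates gated particles over organoid size", {
  a <- array(0, c(1, 2, 1, 20, 20))
  org <- matrix(FALSE, 20, 20); org[2:19, 2:19] <- TRUE
  s <- image_stack(a, channel_names = c("BF", "cYFP"), pixel_size_um = 1)
  parts <- data.frame(id = 1:3, channel = "cYFP", timepoint = 1L, z = 1L,
                      area_um2 = c(50, 60, 5), perimeter_um = 1, circularity = 0.8,
                      total_intensity = c(100, 200, 1000),
                      centroid_x = 1, centroid_y = 1,
                      gate_pass = c(TRUE, TRUE, FALSE))
  cv <- quantify_organoid(s, parts, org, fluorophores = "cYFP")
  expect_equal(cv$value, 300 / sum(org))       # only gate-passing intensity
  expect_equal(cv$normalizer_kind, "organoid_area")
  parts$gate_pass <- FALSE
  expect_equal(quantify_organoid(s, parts, org, fluorophores = "cYFP")$value, 0)
  expect_error(quantify_organoid(s, parts, matrix(FALSE, 20, 20),
                                 fluorophores = "cYFP"), "empty")
})

test_that("leak-through correction removes spurious cYFP in a 0%-cYFP scene", {
  cfg <- scene_config("culture2d", field_size_um = c(256, 256), pixel_size_um = 2,
                      n_timepoints = 2, frame_interval_h = 24, seed = 55)
  sim <- simulate_scene(cfg,
                        recombination_model(background_hazard_per_h = 0.05,
                                            light_hazard_multiplier = 5,
                                            outcome_probs = c(mCFP = 0.3, nGFP = 0.7,
                                                              cYFP = 0, cRFP = 0)),
                        optics_noise_free(leakthrough_lf_true = 0.3,
                                          background_offset = 5),
                        n_cells = 60)
  bs <- subtract_background(sim$stack, sim$truth$rois)
  model <- estimate_leakthrough(sim$stack, "nGFP", "cYFP", rois = sim$truth$rois)
  corr <- correct_leakthrough(bs, model)
  mask <- matrix(sim$truth$label_map[1, , ] > 0, 128, 128)
  raw_y <- quantify_timelapse_2d(bs, mask, "cYFP")$value
  cor_y <- quantify_timelapse_2d(corr, mask, "cYFP")$value
  expect_true(all(cor_y <= 0.05 * raw_y))
})

test_that("z-stack totals are normalized by the number of z-steps", {
  pl <- matrix(runif(64) * 10, 8, 8)
  r <- roi_rect("P1", "photoconverted", 1, 1, 5, 5)
  for (nz in c(1, 3, 6)) {
    a <- array(0, c(1, 1, nz, 8, 8))
    for (z in seq_len(nz)) a[1, 1, z, , ] <- pl
    s <- image_stack(a, channel_names = "eGFP")
    cv <- quantify_zstack(s, r, "eGFP")
    # replicated plane: same value whatever n_z
    expect_equal(cv$value, sum(pl[rasterize_roi(r, c(8, 8))]))
  }
  # single nonzero plane: total divided by n_z
  a <- array(0, c(1, 1, 4, 8, 8)); a[1, 1, 2, , ] <- pl
  s <- image_stack(a, channel_names = "eGFP")
  expect_equal(quantify_zstack(s, r, "eGFP")$value,
               sum(pl[rasterize_roi(r, c(8, 8))]) / 4)
})

test_that("z-stack read-out with one plane equals the ROI-mode 2D read-out", {
  sim <- quick_scene(seed = 57, n_timepoints = 2, offset = 0, n_cells = 40)
  r <- sim$truth$rois[["P1"]]
  mask <- rasterize_roi(r, sim$stack)
  v1 <- quantify_zstack(sim$stack, r, "nGFP")$value
  v2 <- quantify_timelapse_2d(sim$stack, mask, "nGFP", mode = "roi")$value
  expect_equal(v1, v2)
})

test_that("control curves are identically zero without hazard or noise", {
  cfg <- scene_config("culture2d", field_size_um = c(192, 192), pixel_size_um = 2,
                      n_timepoints = 3, frame_interval_h = 12, seed = 61)
  rois <- roi_set(roi_rect("P1", "photoconverted", 8, 8, 30, 30),
                  roi_rect("C1", "control", 60, 60, 30, 30),
                  roi_rect("bg", "background", 70, 8, 20, 14))
  sim <- simulate_scene(cfg, recombination_model(background_hazard_per_h = 0,
                                                 light_hazard_multiplier = 1),
                        optics_noise_free(), rois = rois, n_cells = 30)
  ctrl <- rasterize_roi(rois[["C1"]], sim$stack)
  for (fl in c("mCFP", "nGFP", "cYFP", "cRFP"))
    expect_equal(quantify_timelapse_2d(sim$stack, ctrl, fl, mode = "roi")$value,
                 rep(0, 3))
})

test_that("illuminated skin-like z-stacks rise at least 5-fold over control by 48 h", {
  cfg <- scene_config("culture2d", field_size_um = c(256, 256), pixel_size_um = 2,
                      n_z = 4, z_step_um = 3, n_timepoints = 7,
                      frame_interval_h = 8, seed = 63)
  sim <- simulate_scene(cfg, recombination_model(), optics_model(),
                        n_cells = 60)
  rois <- sim$truth$rois
  bs <- subtract_background(sim$stack, rois)
  tot <- function(lab) Reduce(`+`, lapply(c("mCFP", "nGFP", "cYFP", "cRFP"),
    function(fl) quantify_zstack(bs, rois[[lab]], fl)$value))
  light <- tot("P1"); ctrl <- tot("C1")
  # rectified-noise pedestal is common to both regions; the read-out of
  # interest is the rise over the pre-activation baseline
  post <- which(sim$stack$time_points_h > 0 & sim$stack$time_points_h <= 48)
  rise_light <- light[post] - light[1]
  rise_ctrl <- pmax(ctrl[post] - ctrl[1], 1e-9)
  expect_gte(max(rise_light / rise_ctrl), 5)
})

test_that("depth profiles separate reporter cells from the collagen band", {
  cfg <- scene_config("skin_zstack", field_size_um = c(96, 96), n_z = 12,
                      n_timepoints = 5, frame_interval_h = 48, seed = 65)
  sim <- simulate_skin_relocation(cfg, relocation_day = 5,
                                  optics = optics_model(leakthrough_lf_true = 0.1),
                                  n_cells = 15)
  bs <- subtract_background(sim$stack, sim$truth$rois)
  # several ROIs -> SEM defined; single ROI -> SEM absent
  rois3 <- roi_set(roi_rect("P1", "photoconverted", 8, 8, 36, 36),
                   roi_rect("P2", "photoconverted", 52, 8, 36, 36),
                   roi_rect("P3", "photoconverted", 30, 52, 36, 36))
  zp_pre <- z_profile(bs, rois3, timepoint = 2)   # day 2
  expect_equal(zp_pre$n_rois, 3)
  expect_true(all(is.finite(zp_pre$summary$egfp_sem)))
  zp_one <- z_profile(bs, roi_set(roi_rect("P1", "photoconverted", 8, 8, 36, 36)),
                      timepoint = 2)
  expect_true(all(is.na(zp_one$summary$egfp_sem)))
  expect_equal(zp_one$summary$egfp_mean,
               zp_one$per_roi$egfp_total)
  # before relocation the eGFP peak sits above the SHG peak...
  pre_peak <- which.max(zp_pre$summary$egfp_mean)
  shg_peak <- which.max(zp_pre$summary$shg_mean)
  expect_lt(pre_peak, shg_peak)
  expect_lt(z_centroid_shift(zp_pre), 0)
  # ...and at or below it afterwards (day 6)
  zp_post <- z_profile(bs, rois3, timepoint = 4)
  expect_gte(which.max(zp_post$summary$egfp_mean), shg_peak)
  expect_gte(z_centroid_shift(zp_post), 0)
  expect_error(z_profile(bs, rois3, shg = "nope"), "absent")
})

test_that("the hazard-ratio estimator recovers a known multiplier from clean kinetics", {
  t_h <- seq(0, 40, by = 8)
  plateau <- 7.2
  h_c <- 0.005; m <- 20
  light <- plateau * (1 - exp(-h_c * m * t_h))
  ctrl <- plateau * (1 - exp(-h_c * t_h))
  est <- estimate_hazard_multiplier(t_h, light, ctrl)
  expect_lt(abs(est$multiplier - m) / m, 0.01)
  expect_lt(abs(est$plateau - plateau) / plateau, 0.02)
})
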
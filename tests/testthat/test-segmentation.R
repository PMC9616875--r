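make_band_fixture <- function(seed = 1, size = 48) {
  # three disjoint intensity bands: trivially separable classes
  set.seed(seed)
  lab <- matrix(sample(1:3, size * size, replace = TRUE), size, size)
  img <- matrix(0, size, size)
  img[lab == 1] <- runif(sum(lab == 1), 200, 210)   # foreground
  img[lab == 2] <- runif(sum(lab == 2), 100, 110)   # debris
  img[lab == 3] <- runif(sum(lab == 3), 0, 10)      # background
  list(img = img, lab = lab)
}

test_that("the pixel classifier separates disjoint intensity bands", {
  train <- make_band_fixture(1)
  test <- make_band_fixture(2)
  clf <- train_pixel_classifier(train$img, train$lab, seed = 4)
  pred <- classify_pixels(test$img, clf)
  expect_gte(mean(pred == test$lab), 0.99)
  # foreground mask agrees with the class-1 pixels
  fg <- foreground_mask(test$img, clf)
  expect_gte(mean(fg == (test$lab == 1)), 0.99)
})

test_that("training requires every class to be annotated", {
  f <- make_band_fixture(3)
  lab1 <- f$lab
  lab1[lab1 != 1] <- 0L  # only foreground annotated
  expect_error(train_pixel_classifier(f$img, lab1, seed = 1),
               "debris.*background|missing annotations")
  expect_error(train_pixel_classifier(f$img, f$lab[1:10, 1:10], seed = 1),
               "align")
})

test_that("retraining with the same seed and data reproduces predictions", {
  f <- make_band_fixture(4)
  probe <- make_band_fixture(5)$img
  c1 <- train_pixel_classifier(f$img, f$lab, seed = 11)
  c2 <- train_pixel_classifier(f$img, f$lab, seed = 11)
  expect_identical(classify_pixels(probe, c1), classify_pixels(probe, c2))
  # and a saved/reloaded classifier predicts identically
  path <- tempfile(fileext = ".rds")
  save_classifier(c1, path)
  expect_identical(classify_pixels(probe, load_classifier(path)),
                   classify_pixels(probe, c1))
})

test_that("masks from classifier and Otsu fallback overlap the ground truth", {
  sim <- quick_scene(seed = 41, n_timepoints = 2, offset = 4, n_cells = 50,
                     hazard = 0.2, mult = 1)
  pl <- get_plane(sim$stack, 2, "BF")
  truth_mask <- matrix(sim$truth$label_map[1, , ] > 0, nrow(pl), ncol(pl))
  iou <- function(a, b) sum(a & b) / sum(a | b)
  # train on the scene's own ground truth labels (1 = cells, 2 = background)
  lab <- matrix(2L, nrow(pl), ncol(pl))
  lab[truth_mask] <- 1L
  clf <- train_pixel_classifier(pl, lab, classes = c("cells", "background"),
                                seed = 2, max_pixels_per_class = 2000)
  expect_gte(iou(foreground_mask(pl, clf, "cells"), truth_mask), 0.9)
  expect_gte(iou(otsu_mask(pl), truth_mask), 0.8)
  # an all-background probe yields an empty mask
  expect_equal(sum(otsu_mask(matrix(5, 32, 32))), 0)
  flat <- classify_pixels(matrix(5, 32, 32), clf)
  expect_true(all(flat == flat[1]))
})

test_that("connected components match a brute-force flood fill exactly", {
  set.seed(99)
  for (rep in 1:30) {
    ny <- sample(8:64, 1); nx <- sample(8:64, 1)
    m <- matrix(runif(ny * nx) < runif(1, 0.2, 0.6), ny, nx)
    lab <- label_components(m, 8L)
    oracle <- flood_fill_label(m, 8L)
    expect_equal(max(lab), max(oracle))
    # identical partition: label images agree up to renumbering; since both
    # number by first pixel in column-major order they agree exactly
    expect_identical(lab, oracle)
    lab4 <- label_components(m, 4L)
    expect_equal(max(lab4), max(flood_fill_label(m, 4L)))
  }
})

test_that("particle metrics are invariant to padding and labeling order", {
  set.seed(7)
  m <- matrix(runif(400) < 0.3, 20, 20)
  intens <- matrix(runif(400) * 100, 20, 20)
  pt <- analyze_particles(m, intens, 1)
  pad <- function(x, fill) {
    out <- matrix(fill, 28, 28); out[5:24, 5:24] <- x; out
  }
  pt2 <- analyze_particles(pad(m, FALSE), pad(intens, 0), 1)
  expect_equal(sort(pt$area_um2), sort(pt2$area_um2))
  expect_equal(sort(pt$total_intensity), sort(pt2$total_intensity))
  expect_equal(sort(pt$perimeter_um), sort(pt2$perimeter_um))
  expect_equal(sum(pt$total_intensity), sum(intens[m]))
})

test_that("circularity of rasterized ellipses decreases with eccentricity", {
  # roughly constant area pi*a*b = pi*64
  axes <- list(c(8, 8), c(10, 6.4), c(12.8, 5), c(16, 4), c(20, 3.2))
  circ <- vapply(axes, function(ab) {
    m <- make_ellipse(ab[1], ab[2], size = 48)
    analyze_particles(m, pixel_size_um = 1)$circularity
  }, 0)
  expect_true(all(diff(circ) < 0))
  expect_gte(circ[1], 0.9)  # the disc end of the family
})

test_that("analytic disc and square circularities hold under the declared conventions", {
  d <- make_disc(10)
  pd <- analyze_particles(d, pixel_size_um = 1, perimeter_method = "contour")
  expect_equal(pd$area_um2, sum(d))
  expect_lt(abs(pd$area_um2 - pi * 100) / (pi * 100), 0.02)
  expect_gte(pd$circularity, 0.9)
  sq <- matrix(FALSE, 8, 8); sq[3:6, 3:6] <- TRUE
  ps <- analyze_particles(sq, pixel_size_um = 1, perimeter_method = "boundary")
  expect_equal(ps$circularity, pi / 4, tolerance = 1e-6)
  # raw marching-squares length of the square: 4 sides of 3 plus 4 cut corners
  pr <- analyze_particles(sq, pixel_size_um = 1, perimeter_method = "contour",
                          contour_correction = 1)
  expect_equal(pr$perimeter_um, 12 + 4 * sqrt(0.5), tolerance = 1e-9)
})

test_that("fluorophore gates pass and fail particles as published", {
  # nGFP-sized nucleus: ~40 um^2 disc passes the 20-70 / 0.5-1 gate
  nucleus <- make_disc(3.57)  # pi*r^2 ~ 40
  g <- gate_profile("organoid")
  pn <- analyze_particles(nucleus, pixel_size_um = 1, gate = g$nGFP)
  expect_true(pn$gate_pass)
  # a 15 um^2 fragment fails the same gate on area
  frag <- make_disc(2.18)
  pf <- analyze_particles(frag, pixel_size_um = 1, gate = g$nGFP)
  expect_false(pf$gate_pass)
  expect_error(particle_gate("x", 10, 5, 0, 1), "min <= max")
  expect_error(particle_gate("x", 5, 10, 0, 1.2), "\\[0, 1\\]")
})

test_that("organoid and in-vivo gate profiles select different survivor sets", {
  # spanning fixture: discs whose areas sweep 10..6000 um^2
  radii <- sqrt(c(10, 25, 50, 80, 150, 400, 900, 2000, 4500, 6000) / pi)
  tables <- lapply(radii, function(r) {
    m <- make_disc(r, size = 2 * ceiling(r) + 7)
    analyze_particles(m, pixel_size_um = 1)
  })
  masks <- lapply(radii, function(r) make_disc(r, size = 2 * ceiling(r) + 7))
  tab <- do.call(rbind, tables)
  survivors <- list()
  for (profile in c("organoid", "invivo")) {
    gates <- gate_profile(profile)
    for (fl in names(gates)) {
      gate <- gates[[fl]]
      # verdicts from the gated particle-analysis path...
      got <- vapply(masks, function(m)
        analyze_particles(m, pixel_size_um = 1, gate = gate)$gate_pass, TRUE)
      # ...must match the exhaustive check on the measured morphometrics
      want <- tab$area_um2 >= gate$area_min_um2 & tab$area_um2 <= gate$area_max_um2 &
        tab$circularity >= gate$circ_min & tab$circularity <= gate$circ_max
      expect_equal(got, want, info = paste(profile, fl))
      survivors[[paste(profile, fl)]] <- which(got)
    }
  }
  # the two profiles keep different survivor sets on the spanning fixture
  expect_false(identical(survivors[["organoid mCFP"]], survivors[["invivo mCFP"]]))
  expect_false(identical(survivors[["organoid nGFP"]], survivors[["invivo nGFP"]]))
})

test_that("an empty mask yields an empty particle table, not an error", {
  pt <- analyze_particles(matrix(FALSE, 10, 10), pixel_size_um = 1)
  expect_s3_class(pt, "particle_table")
  expect_equal(nrow(pt), 0)
  expect_warning(analyze_particles(matrix(c(rep(FALSE, 99), TRUE), 10, 10),
                                   pixel_size_um = NA),
                 "px")
})
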
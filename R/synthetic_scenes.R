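#' Scene configuration for the synthetic microscopy generator
#'
#' Defines the geometry and sampling of a simulated experiment. Three
#' geometries are supported, mirroring common photoactivation study
#' designs: `culture2d` (sparse adherent cells, single plane, short frame
#' interval), `organoid` (a round cell cluster analyzed on a projection
#' plane, 90-min cadence) and `skin_zstack` (a layered epidermis/basal/
#' dermis tissue with a collagen second-harmonic band, imaged daily as a
#' z-stack with 3 um steps).
#'
#' @param geometry One of `"culture2d"`, `"organoid"`, `"skin_zstack"`.
#' @param field_size_um Length-2 (width, height) of the field in um; must
#'   be an integer multiple of `pixel_size_um`.
#' @param pixel_size_um Lateral pixel size in um (geometry default: 2 for
#'   culture2d/organoid overview scans, 1 for skin stacks).
#' @param n_z Number of z-slices; must be 1 for `culture2d`.
#' @param z_step_um Axial step in um.
#' @param n_timepoints Number of frames.
#' @param frame_interval_h Time between frames in hours.
#' @param seed Integer seed; every stochastic element of the scene derives
#'   from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(geometry = c("culture2d", "organoid", "skin_zstack"),
                         field_size_um = NULL, pixel_size_um = 1,
                         n_z = NULL, z_step_um = 3,
                         n_timepoints = NULL, frame_interval_h = NULL,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  defaults <- switch(geometry,
    culture2d  = list(field = c(512, 512), px = 2, n_z = 1L,  n_t = 8L,  dt = 0.5),
    organoid   = list(field = c(480, 480), px = 2, n_z = 1L,  n_t = 28L, dt = 1.5),
    skin_zstack = list(field = c(128, 128), px = 1, n_z = 12L, n_t = 9L,  dt = 24))
  if (missing(pixel_size_um)) pixel_size_um <- defaults$px
  field_size_um <- field_size_um %||% defaults$field
  n_z <- as.integer(n_z %||% defaults$n_z)
  n_timepoints <- as.integer(n_timepoints %||% defaults$n_t)
  frame_interval_h <- frame_interval_h %||% defaults$dt
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(z_step_um, "z_step_um")
  check_positive(frame_interval_h, "frame_interval_h")
  if (length(field_size_um) != 2L || any(field_size_um <= 0))
    stopf("`field_size_um` must be two positive numbers")
  npx <- field_size_um / pixel_size_um
  if (any(abs(npx - round(npx)) > 1e-9))
    stopf("field_size_um / pixel_size_um must give integer pixel dimensions")
  if (n_z < 1L) stopf("`n_z` must be >= 1")
  if (geometry == "skin_zstack" && n_z < 6L)
    stopf("skin_zstack needs n_z >= 6 to span epidermis, basal layer, collagen band and dermis")
  if (n_timepoints < 1L) stopf("`n_timepoints` must be >= 1")
  structure(list(geometry = geometry, field_size_um = as.numeric(field_size_um),
                 pixel_size_um = pixel_size_um, n_z = n_z, z_step_um = z_step_um,
                 n_timepoints = n_timepoints, frame_interval_h = frame_interval_h,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Recombination model for optogenetic Cre
#'
#' Recombination is modeled as a per-cell hazard: cells expressing the
#' light-activatable Cre (doxycycline present) recombine at
#' `background_hazard_per_h` from leaky uncaging; inside an illuminated
#' region, after the illumination time, the hazard is multiplied by
#' `light_hazard_multiplier`. Upon illumination the photoswitchable
#' Cre-fusion converts a fraction of its green fluorescence to red, which
#' then decays exponentially as the cleaved protein is lost. A recombined
#' cell permanently expresses one stochastic multicolor-reporter outcome.
#'
#' @param background_hazard_per_h Leaky recombination hazard (per hour),
#'   applies when the driver is expressed (doxycycline present).
#' @param light_hazard_multiplier Hazard fold-increase inside illuminated
#'   ROIs after illumination; must be >= 1.
#' @param photoswitch_fraction Fraction of the driver's green signal
#'   converted green-to-red on illumination, in `[0, 1]`.
#' @param red_decay_halflife_h Half-life (hours) of the photoswitched red
#'   signal. The underlying kinetics are not quantified in the source
#'   system, so this is configurable; default 1 h ("disappears within
#'   minutes to hours").
#' @param outcome_probs Probability vector over reporter outcomes
#'   `mCFP` (membrane), `nGFP` (nuclear), `cYFP`, `cRFP` (cytoplasmic);
#'   must sum to 1.
#' @param illumination_time_h Time of the 405 nm pulse (hours); hazard is
#'   elevated for `t > illumination_time_h`.
#' @return A `recombination_model` list.
#' @export
recombination_model <- function(background_hazard_per_h = 0.005,
                                light_hazard_multiplier = 20,
                                photoswitch_fraction = 0.8,
                                red_decay_halflife_h = 1,
                                outcome_probs = c(mCFP = 0.25, nGFP = 0.25,
                                                  cYFP = 0.25, cRFP = 0.25),
                                illumination_time_h = 0) {
  check_nonneg(background_hazard_per_h, "background_hazard_per_h")
  if (!is_scalar_num(light_hazard_multiplier) || light_hazard_multiplier < 1)
    stopf("`light_hazard_multiplier` must be >= 1")
  if (!is_scalar_num(photoswitch_fraction) || photoswitch_fraction < 0 || photoswitch_fraction > 1)
    stopf("`photoswitch_fraction` must be in [0, 1]")
  check_positive(red_decay_halflife_h, "red_decay_halflife_h")
  req <- c("mCFP", "nGFP", "cYFP", "cRFP")
  if (!all(req %in% names(outcome_probs)))
    stopf("`outcome_probs` must be named with %s", paste(req, collapse = ", "))
  outcome_probs <- outcome_probs[req]
  if (any(outcome_probs < 0) || abs(sum(outcome_probs) - 1) > 1e-12)
    stopf("`outcome_probs` must be nonnegative and sum to 1 (got %.15g)", sum(outcome_probs))
  check_nonneg(illumination_time_h, "illumination_time_h")
  structure(list(background_hazard_per_h = background_hazard_per_h,
                 light_hazard_multiplier = light_hazard_multiplier,
                 photoswitch_fraction = photoswitch_fraction,
                 red_decay_halflife_h = red_decay_halflife_h,
                 outcome_probs = outcome_probs,
                 illumination_time_h = illumination_time_h),
            class = "recombination_model")
}

#' Optical corruption model
#'
#' Describes how ideal fluorophore maps become recorded images: spectral
#' leak-through mixing (nuclear-GFP emission detected in the YFP channel,
#' or green driver signal in the red channel for the skin geometry),
#' per-channel additive background offset, depth-dependent signal
#' attenuation, and Poisson (shot) plus Gaussian (read) noise.
#'
#' @param leakthrough_lf_true True mixing coefficient from the source into
#'   the target channel (nGFP -> cYFP; eGFP -> red for skin).
#' @param background_offset Per-channel additive offset; a single value is
#'   recycled to all channels.
#' @param gaussian_sd Read-noise standard deviation (0 disables).
#' @param poisson_gain Shot-noise gain g: recorded = g * Poisson(signal/g)
#'   (0 disables).
#' @param z_attenuation_per_um Exponential intensity attenuation per um of
#'   depth.
#' @return An `optics_model` list.
#' @export
optics_model <- function(leakthrough_lf_true = 0.15, background_offset = 10,
                         gaussian_sd = 2, poisson_gain = 0.5,
                         z_attenuation_per_um = 0.01) {
  check_nonneg(leakthrough_lf_true, "leakthrough_lf_true")
  check_nonneg(background_offset, "background_offset")
  check_nonneg(gaussian_sd, "gaussian_sd")
  check_nonneg(poisson_gain, "poisson_gain")
  check_nonneg(z_attenuation_per_um, "z_attenuation_per_um")
  structure(list(leakthrough_lf_true = leakthrough_lf_true,
                 background_offset = background_offset,
                 gaussian_sd = gaussian_sd, poisson_gain = poisson_gain,
                 z_attenuation_per_um = z_attenuation_per_um),
            class = "optics_model")
}

#' Noise-free optics (for oracle tests)
#' @inheritParams optics_model
#' @return An `optics_model` with noise terms zeroed.
#' @export
optics_noise_free <- function(leakthrough_lf_true = 0, background_offset = 0,
                              z_attenuation_per_um = 0) {
  optics_model(leakthrough_lf_true = leakthrough_lf_true,
               background_offset = background_offset,
               gaussian_sd = 0, poisson_gain = 0,
               z_attenuation_per_um = z_attenuation_per_um)
}

CONFETTI <- c("mCFP", "nGFP", "cYFP", "cRFP")
CULTURE_CHANNELS <- c("BF", "DiLiCre_green", "DiLiCre_red", CONFETTI)
SKIN_CHANNELS <- c("eGFP", "red_empty", "SHG")

#' Default per-pixel emission levels of the generator
#' @return Named list of intensity levels (arbitrary units per pixel).
#' @export
scene_levels <- function() {
  list(bf = 40, dilicre = 60, confetti = 100, egfp = 100, shg = 80)
}

#' Default ROI layout for a scene geometry
#'
#' `culture2d`: a photoconverted square and a matched control square in
#' opposite corners (centers ~190 um apart), a cell-free background
#' rectangle and a reference rectangle (seeded with nuclear-GFP-only cells
#' for leak-through estimation). `organoid`: a photoconverted square
#' covering the whole organoid, plus background and reference rectangles
#' in the margins. `skin_zstack`: a photoconverted square in the field
#' center plus a background corner.
#'
#' @param config A [scene_config()].
#' @return An [roi_set()].
#' @export
default_scene_rois <- function(config) {
  nx <- config$field_size_um[1] / config$pixel_size_um
  ny <- config$field_size_um[2] / config$pixel_size_um
  switch(config$geometry,
    culture2d = roi_set(
      roi_rect("P1", "photoconverted", 0.12 * nx, 0.12 * ny, 0.23 * nx, 0.23 * ny),
      roi_rect("C1", "control", 0.65 * nx, 0.65 * ny, 0.23 * nx, 0.23 * ny),
      roi_rect("bg", "background", 0.78 * nx, 0.04 * ny, 0.18 * nx, 0.12 * ny),
      roi_rect("ref", "reference", 0.04 * nx, 0.80 * ny, 0.18 * nx, 0.16 * ny)),
    organoid = roi_set(
      roi_rect("P1", "photoconverted", 0.03 * nx, 0.03 * ny, 0.94 * nx, 0.94 * ny),
      roi_rect("bg", "background", 0.005 * nx, 0.005 * ny, 0.14 * nx, 0.14 * ny),
      roi_rect("ref", "reference", 0.40 * nx, 0.40 * ny, 0.12 * nx, 0.12 * ny)),
    skin_zstack = roi_set(
      roi_rect("P1", "photoconverted", 0.25 * nx, 0.25 * ny, 0.5 * nx, 0.5 * ny),
      roi_rect("bg", "background", 0.02 * nx, 0.02 * ny, 0.12 * nx, 0.12 * ny)))
}

# ---- cell rendering -------------------------------------------------------

# rasterize an ellipse (center cx,cy px; semi-axes a,b px; angle rad) into
# linear indices of an ny x nx matrix, using the pixel-center rule
ellipse_indices <- function(cx, cy, a, b, theta, ny, nx) {
  r <- max(a, b)
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r + 1))
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r + 1))
  if (length(xs) == 0L || length(ys) == 0L) return(integer(0))
  px <- rep(xs - 0.5, each = length(ys)) - cx
  py <- rep(ys - 0.5, times = length(xs)) - cy
  u <- (px * cos(theta) + py * sin(theta)) / a
  w <- (-px * sin(theta) + py * cos(theta)) / b
  keep <- (u * u + w * w) <= 1
  iy <- rep(ys, times = length(xs))[keep]
  ix <- rep(xs, each = length(ys))[keep]
  (ix - 1L) * ny + iy
}

# 1-pixel 8-neighbour erosion of a pixel index set
erode_indices <- function(idx, ny) {
  if (length(idx) == 0L) return(idx)
  present <- new.env(hash = TRUE, size = length(idx) * 2L)
  for (i in idx) assign(as.character(i), TRUE, envir = present)
  off <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
  keep <- vapply(idx, function(i) {
    all(vapply(off, function(o) exists(as.character(i + o), envir = present), TRUE))
  }, TRUE)
  # boundary columns/rows: neighbour indices past array edges never exist in
  # the set, so edge pixels are correctly eroded away
  idx[keep]
}

# build the compartment masks of one cell; returns list of linear indices
render_cell <- function(cx, cy, a, b, theta, ny, nx) {
  fp <- ellipse_indices(cx, cy, a, b, theta, ny, nx)
  interior <- erode_indices(fp, ny)
  nucleus <- ellipse_indices(cx, cy, 0.4 * a, 0.4 * b, theta, ny, nx)
  nucleus <- intersect(nucleus, interior)
  list(footprint = fp,
       membrane = setdiff(fp, interior),
       nucleus = nucleus,
       cytoplasm = setdiff(interior, nucleus))
}

compartment_for <- function(outcome) {
  switch(outcome, mCFP = "membrane", nGFP = "nucleus",
         cYFP = "cytoplasm", cRFP = "cytoplasm")
}

# jittered-grid placement of non-overlapping cell centers inside `allowed`
# (logical ny x nx matrix); returns data.frame(cx, cy)
place_cells <- function(n_cells, allowed, spacing_px, margin_px) {
  ny <- nrow(allowed); nx <- ncol(allowed)
  gx <- seq(spacing_px / 2, nx - spacing_px / 2, by = spacing_px)
  gy <- seq(spacing_px / 2, ny - spacing_px / 2, by = spacing_px)
  pts <- expand.grid(cx = gx, cy = gy)
  ok <- allowed[cbind(pmin(ny, pmax(1L, round(pts$cy))),
                      pmin(nx, pmax(1L, round(pts$cx))))]
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) < n_cells)
    stopf("field too small for %d non-overlapping cells (capacity %d)", n_cells, nrow(pts))
  pts <- pts[sample.int(nrow(pts), n_cells), , drop = FALSE]
  jit <- max(0, margin_px)
  pts$cx <- pts$cx + stats::runif(n_cells, -jit, jit)
  pts$cy <- pts$cy + stats::runif(n_cells, -jit, jit)
  pts
}

# sample recombination times under a piecewise-constant hazard
sample_recomb_times <- function(n, hazard0, mult_eff, t_ill) {
  e <- stats::rexp(n)
  t <- rep(Inf, n)
  if (hazard0 > 0) {
    pre <- e <= hazard0 * t_ill
    t[pre] <- e[pre] / hazard0
    post <- !pre & mult_eff > 0
    t[post] <- t_ill + (e[post] - hazard0 * t_ill) / (hazard0 * mult_eff)
  }
  t
}

apply_noise <- function(arr, optics) {
  if (optics$poisson_gain > 0) {
    g <- optics$poisson_gain
    arr[] <- stats::rpois(length(arr), arr / g) * g
  }
  if (optics$gaussian_sd > 0)
    arr[] <- arr + stats::rnorm(length(arr), 0, optics$gaussian_sd)
  arr[arr < 0] <- 0
  arr
}

with_scene_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a photoactivation scene
#'
#' Generates a calibrated multichannel time-lapse (channels: brightfield,
#' driver green/red, and the four multicolor-reporter channels) together
#' with full ground truth. Cells are non-overlapping ellipses with
#' compartment masks (membrane ring, concentric nucleus at 40% linear
#' size, cytoplasm); the driver is expressed when doxycycline is present
#' (`condition` contains dox); illumination photoswitches the driver
#' green-to-red inside photoconverted ROIs and multiplies the
#' recombination hazard there. The noise-free per-fluorophore maps are
#' kept in the ground truth (`truth$clean`) before leak-through mixing,
#' background offset and noise are applied to the recorded stack.
#'
#' Cells whose centroid falls inside a `reference` ROI are rendered as
#' pre-existing nuclear-GFP-only cells (recombination time 0), emulating
#' the analyst's choice of a single-fluorophore reference region for
#' leak-through estimation.
#'
#' @param config A [scene_config()] with geometry `culture2d` or
#'   `organoid`.
#' @param recomb A [recombination_model()].
#' @param optics An [optics_model()].
#' @param rois An [roi_set()]; defaults to [default_scene_rois()].
#' @param condition Experimental condition: `"light_dox"` (illuminated,
#'   driver expressed), `"dox_only"`, `"light_only"`, `"untreated"`.
#'   Without doxycycline the driver is absent and the recombination hazard
#'   is zero; without light no ROI is photoconverted.
#' @param n_cells Number of cells (default 200 for organoid, 150 for
#'   culture2d).
#' @param cell_radius_um Mean cell semi-major axis in um.
#' @param store_clean Keep the noise-free pre-mixing channel array in the
#'   ground truth (needed by oracle tests; default TRUE).
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (class `ground_truth`: `cells` data frame, `label_map` integer
#'   (Z,Y,X) array of cell ids over footprints, `clean` noise-free array,
#'   `config`, `condition`).
#' @export
simulate_scene <- function(config, recomb = recombination_model(),
                           optics = optics_model(), rois = NULL,
                           condition = c("light_dox", "dox_only", "light_only", "untreated"),
                           n_cells = NULL, cell_radius_um = 9,
                           store_clean = TRUE) {
  condition <- match.arg(condition)
  if (!inherits(config, "scene_config")) stopf("`config` must be a scene_config")
  if (config$geometry == "skin_zstack")
    stopf("use simulate_skin_relocation() for the skin_zstack geometry")
  if (abs(sum(recomb$outcome_probs) - 1) > 1e-12)
    stopf("outcome_probs must sum to 1")
  rois <- rois %||% default_scene_rois(config)
  nx <- as.integer(round(config$field_size_um[1] / config$pixel_size_um))
  ny <- as.integer(round(config$field_size_um[2] / config$pixel_size_um))
  for (r in rois)
    if (any(r$vertices[, 1] < 0 | r$vertices[, 1] > nx |
            r$vertices[, 2] < 0 | r$vertices[, 2] > ny))
      stopf("ROI '%s' lies outside the %dx%d px field", r$label, ny, nx)
  n_cells <- n_cells %||% if (config$geometry == "organoid") 200L else 150L
  dox <- condition %in% c("light_dox", "dox_only")
  light <- condition %in% c("light_dox", "light_only")
  lv <- scene_levels()

  with_scene_seed(config$seed, {
    # admissible region: inside organoid disc (organoid) or anywhere
    # (culture2d), excluding the background ROI margin
    allowed <- matrix(TRUE, ny, nx)
    if (config$geometry == "organoid") {
      cx0 <- nx / 2; cy0 <- ny / 2; R <- 0.45 * min(nx, ny)
      xs <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
      ysm <- matrix(rep(seq_len(ny) - 0.5, times = nx), ny, nx)
      allowed <- ((xs - cx0)^2 + (ysm - cy0)^2) <= R^2
    }
    for (r in rois_by_role(rois, "background")) {
      m <- rasterize_roi(r, c(ny, nx))
      # dilate exclusion by the cell radius so no cell touches the ROI
      allowed[m] <- FALSE
      pad <- ceiling(cell_radius_um / config$pixel_size_um * 1.3) + 1
      v <- r$vertices
      x1 <- max(1, floor(min(v[, 1])) - pad); x2 <- min(nx, ceiling(max(v[, 1])) + pad)
      y1 <- max(1, floor(min(v[, 2])) - pad); y2 <- min(ny, ceiling(max(v[, 2])) + pad)
      allowed[y1:y2, x1:x2] <- FALSE
    }
    a_mean <- cell_radius_um / config$pixel_size_um
    a_max <- 1.2 * a_mean
    spacing <- 2 * (a_max + 0.5) + 0.6
    pts <- place_cells(n_cells, allowed, spacing, (spacing - 2 * (a_max + 0.5)) / 2)

    a <- stats::runif(n_cells, 0.85, 1.2) * a_mean
    b <- stats::runif(n_cells, 0.7, 1.0) * a
    th <- stats::runif(n_cells, 0, pi)
    zi <- if (config$n_z > 1L) sample.int(config$n_z, n_cells, replace = TRUE) else rep(1L, n_cells)

    cells <- lapply(seq_len(n_cells), function(i)
      render_cell(pts$cx[i], pts$cy[i], a[i], b[i], th[i], ny, nx))

    # membership in photoconverted / reference ROIs by centroid
    pc_mask <- Reduce(`|`, lapply(rois_by_role(rois, "photoconverted"),
                                  rasterize_roi, dim_yx = c(ny, nx)),
                      accumulate = FALSE, init = matrix(FALSE, ny, nx))
    ref_mask <- Reduce(`|`, lapply(rois_by_role(rois, "reference"),
                                   rasterize_roi, dim_yx = c(ny, nx)),
                       accumulate = FALSE, init = matrix(FALSE, ny, nx))
    ci <- cbind(pmin(ny, pmax(1L, round(pts$cy))), pmin(nx, pmax(1L, round(pts$cx))))
    in_pc <- pc_mask[ci]
    # any footprint overlap with a reference region forces the nGFP-only
    # outcome there, so the reference truly contains source-only signal
    in_ref <- vapply(cells, function(cc) any(ref_mask[cc$footprint]), TRUE)

    hazard0 <- if (dox) recomb$background_hazard_per_h else 0
    t_ill <- recomb$illumination_time_h
    mult <- ifelse(in_pc & light, recomb$light_hazard_multiplier, 1)
    t_rec <- sample_recomb_times(n_cells, hazard0, mult, t_ill)
    outcome <- sample(CONFETTI, n_cells, replace = TRUE, prob = recomb$outcome_probs)
    outcome[in_ref] <- "nGFP"
    t_rec[in_ref] <- 0

    time_h <- (seq_len(config$n_timepoints) - 1) * config$frame_interval_h
    nt <- config$n_timepoints; nzp <- config$n_z
    atten <- exp(-optics$z_attenuation_per_um * (zi - 1L) * config$z_step_um)
    comp_name <- vapply(outcome, compartment_for, "")
    comp_n <- vapply(seq_len(n_cells), function(i) length(cells[[i]][[comp_name[i]]]), 0L)
    brightness_total <- lv$confetti * comp_n  # pre-attenuation integrated signal

    clean <- array(0, c(nt, length(CULTURE_CHANNELS), nzp, ny, nx))
    ch_of <- stats::setNames(seq_along(CULTURE_CHANNELS), CULTURE_CHANNELS)
    planes0 <- function() matrix(0, ny, nx)
    for (t in seq_len(nt)) {
      tt <- time_h[t]
      pl <- lapply(CULTURE_CHANNELS, function(x) lapply(seq_len(nzp), function(z) planes0()))
      names(pl) <- CULTURE_CHANNELS
      switched <- in_pc & light & tt >= t_ill
      red_gain <- recomb$photoswitch_fraction *
        2^(-(pmax(0, tt - t_ill)) / recomb$red_decay_halflife_h)
      for (i in seq_len(n_cells)) {
        z <- zi[i]; at <- atten[i]; cc <- cells[[i]]
        pl$BF[[z]][cc$footprint] <- pl$BF[[z]][cc$footprint] + lv$bf * at
        if (dox) {
          gfrac <- if (switched[i]) 1 - recomb$photoswitch_fraction else 1
          pl$DiLiCre_green[[z]][cc$cytoplasm] <-
            pl$DiLiCre_green[[z]][cc$cytoplasm] + lv$dilicre * gfrac * at
          if (switched[i])
            pl$DiLiCre_red[[z]][cc$cytoplasm] <-
              pl$DiLiCre_red[[z]][cc$cytoplasm] + lv$dilicre * red_gain * at
        }
        if (t_rec[i] <= tt) {
          idx <- cc[[comp_name[i]]]
          ch <- outcome[i]
          pl[[ch]][[z]][idx] <- pl[[ch]][[z]][idx] + lv$confetti * at
        }
      }
      for (ch in CULTURE_CHANNELS) for (z in seq_len(nzp))
        clean[t, ch_of[[ch]], z, , ] <- pl[[ch]][[z]]
    }

    recorded <- clean
    # nGFP leaks into the cYFP detection band
    recorded[, ch_of[["cYFP"]], , , ] <- recorded[, ch_of[["cYFP"]], , , ] +
      optics$leakthrough_lf_true * recorded[, ch_of[["nGFP"]], , , ]
    offs <- rep(optics$background_offset, length.out = length(CULTURE_CHANNELS))
    for (ch in seq_along(CULTURE_CHANNELS))
      recorded[, ch, , , ] <- recorded[, ch, , , ] + offs[ch]
    recorded <- apply_noise(recorded, optics)

    label_map <- array(0L, c(nzp, ny, nx))
    for (i in seq_len(n_cells)) {
      plane <- matrix(label_map[zi[i], , ], ny, nx)
      plane[cells[[i]]$footprint] <- i
      label_map[zi[i], , ] <- plane
    }

    stack <- image_stack(recorded, channel_names = CULTURE_CHANNELS,
                         pixel_size_um = config$pixel_size_um,
                         z_step_um = config$z_step_um, time_points_h = time_h)
    truth <- structure(list(
      cells = data.frame(
        id = seq_len(n_cells), outcome = outcome, recomb_time_h = t_rec,
        x_px = pts$cx, y_px = pts$cy, z_index = zi, layer = NA_character_,
        brightness_total = brightness_total, z_attenuation = atten,
        inside_photoconverted = in_pc, forced_reference = in_ref,
        stringsAsFactors = FALSE),
      label_map = label_map,
      clean = if (store_clean) clean,
      channel_names = CULTURE_CHANNELS,
      config = config, condition = condition, rois = rois
    ), class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Per-pixel cell-id label image at a timepoint
#'
#' @param truth A `ground_truth`.
#' @param t Timepoint index.
#' @param expressed_only If TRUE (default) only cells already expressing a
#'   reporter fluorophore at `t` are labeled.
#' @return Integer (Z, Y, X) array of cell ids (0 = no cell).
#' @export
truth_label_image <- function(truth, t = 1L, expressed_only = TRUE) {
  lm <- truth$label_map
  if (!expressed_only) return(lm)
  tt <- (t - 1) * truth$config$frame_interval_h
  keep <- which(truth$cells$recomb_time_h <= tt)
  lm[!(lm %in% keep)] <- 0L
  lm
}

#' Simulate a layered-skin z-stack with programmable cell relocation
#'
#' Builds a daily-imaged z-stack of an epidermis/basal/dermis geometry:
#' oncogene-reporter (eGFP) cells sit in the basal layer, a static
#' fibrillar-collagen band (second-harmonic channel, SHG) separates the
#' basal layer from the dermis, and from `relocation_day` onward the eGFP
#' cells relocate below the collagen band into the dermis. Channels:
#' `eGFP`, `red_empty` (receives only leak-through from the green channel)
#' and `SHG`. The SHG pattern is generated once and reused at every
#' timepoint, so its noise-free per-z profile is time-invariant.
#'
#' @param config A [scene_config()] with geometry `skin_zstack`; time is
#'   interpreted in days via `frame_interval_h` (default 24 h).
#' @param relocation_day Day (real) at which cells move to the dermis; a
#'   value beyond the simulated span produces a static scene with a
#'   warning.
#' @param optics An [optics_model()].
#' @param n_cells Number of eGFP cells.
#' @param cell_radius_um Cell semi-major axis in um.
#' @param store_clean Keep the noise-free array in the truth.
#' @return As [simulate_scene()]: list(stack, truth). `truth$cells$layer`
#'   is the initial layer; `truth$layers` gives the z-index ranges and
#'   `truth$shg_peak_z` the band's peak slice.
#' @export
simulate_skin_relocation <- function(config, relocation_day = 5,
                                     optics = optics_model(),
                                     n_cells = 30, cell_radius_um = 4,
                                     store_clean = TRUE) {
  if (!inherits(config, "scene_config") || config$geometry != "skin_zstack")
    stopf("`config` must be a scene_config with geometry 'skin_zstack'")
  nx <- as.integer(round(config$field_size_um[1] / config$pixel_size_um))
  ny <- as.integer(round(config$field_size_um[2] / config$pixel_size_um))
  nz <- config$n_z
  time_h <- (seq_len(config$n_timepoints) - 1) * config$frame_interval_h
  days <- time_h / 24
  if (is.finite(relocation_day) && relocation_day > max(days))
    warnf("relocation_day = %g is beyond the simulated span (max day %g); scene is static",
          relocation_day, max(days))
  # layer geometry (1-based z, top = surface)
  e_end <- max(1L, round(nz * 0.25))
  b_end <- max(e_end + 1L, round(nz * 0.5))
  s_end <- min(nz - 1L, max(b_end + 1L, round(nz * 0.7)))
  layers <- list(epidermis = c(1L, e_end), basal = c(e_end + 1L, b_end),
                 shg_band = c(b_end + 1L, s_end), dermis = c(s_end + 1L, nz))
  lv <- scene_levels()

  with_scene_seed(config$seed, {
    allowed <- matrix(TRUE, ny, nx)
    a_mean <- cell_radius_um / config$pixel_size_um
    spacing <- 2 * (1.2 * a_mean + 0.5) + 0.6
    pts <- place_cells(n_cells, allowed, spacing, 0.3)
    a <- stats::runif(n_cells, 0.85, 1.15) * a_mean
    b <- stats::runif(n_cells, 0.75, 1.0) * a
    th <- stats::runif(n_cells, 0, pi)
    z_pre <- sample(seq(layers$basal[1], layers$basal[2]), n_cells, replace = TRUE)
    z_post <- sample(seq(layers$dermis[1], layers$dermis[2]), n_cells, replace = TRUE)

    # static collagen texture: smoothed random fibers, weighted per band slice
    fibers <- matrix(0, ny, nx)
    n_fib <- round(ny / 4)
    for (k in seq_len(n_fib)) {
      y0 <- stats::runif(1, 1, ny); amp <- stats::runif(1, 0.5, 1.5)
      slope <- stats::runif(1, -0.15, 0.15)
      yy <- y0 + slope * (seq_len(nx) - nx / 2)
      for (j in seq_len(nx)) {
        i <- round(yy[j])
        if (i >= 1 && i <= ny) fibers[i, j] <- fibers[i, j] + amp
      }
    }
    fibers <- as.matrix(EBImage::gblur(fibers, sigma = 1.2))
    fibers <- fibers / max(mean(fibers), 1e-9)  # mean ~ 1
    band_z <- seq(layers$shg_band[1], layers$shg_band[2])
    band_w <- stats::dnorm(band_z, mean = mean(band_z), sd = max(0.7, length(band_z) / 3))
    band_w <- band_w / max(band_w)

    nt <- config$n_timepoints
    clean <- array(0, c(nt, length(SKIN_CHANNELS), nz, ny, nx))
    ch_of <- stats::setNames(seq_along(SKIN_CHANNELS), SKIN_CHANNELS)
    # ellipsoid rendering: central slice full size, +-1 slice at 60%
    render_at <- function(arr_t_ch, z, idx, val) {
      pl <- matrix(arr_t_ch[z, , ], ny, nx); pl[idx] <- pl[idx] + val; arr_t_ch[z, , ] <- pl
      arr_t_ch
    }
    cell_idx_full <- lapply(seq_len(n_cells), function(i)
      ellipse_indices(pts$cx[i], pts$cy[i], a[i], b[i], th[i], ny, nx))
    cell_idx_small <- lapply(seq_len(n_cells), function(i)
      ellipse_indices(pts$cx[i], pts$cy[i], 0.6 * a[i], 0.6 * b[i], th[i], ny, nx))
    brightness_total <- numeric(n_cells)

    for (t in seq_len(nt)) {
      relocated <- is.finite(relocation_day) && days[t] >= relocation_day
      zc <- if (relocated) z_post else z_pre
      eg <- array(0, c(nz, ny, nx))
      for (i in seq_len(n_cells)) {
        att <- function(z) exp(-optics$z_attenuation_per_um * (z - 1) * config$z_step_um)
        eg <- render_at(eg, zc[i], cell_idx_full[[i]], lv$egfp * att(zc[i]))
        for (dz in c(-1L, 1L)) {
          z2 <- zc[i] + dz
          if (z2 >= 1L && z2 <= nz)
            eg <- render_at(eg, z2, cell_idx_small[[i]], lv$egfp * att(z2))
        }
      }
      if (t == 1L) {
        for (i in seq_len(n_cells)) {
          n_main <- length(cell_idx_full[[i]])
          n_side <- sum(vapply(c(-1L, 1L), function(dz) {
            z2 <- zc[i] + dz
            if (z2 >= 1L && z2 <= nz) length(cell_idx_small[[i]]) else 0L
          }, 0L))
          brightness_total[i] <- lv$egfp * (n_main + n_side)
        }
      }
      clean[t, ch_of[["eGFP"]], , , ] <- eg
      for (k in seq_along(band_z)) {
        z <- band_z[k]
        clean[t, ch_of[["SHG"]], z, , ] <-
          lv$shg * band_w[k] * fibers * exp(-optics$z_attenuation_per_um * (z - 1) * config$z_step_um)
      }
    }

    recorded <- clean
    recorded[, ch_of[["red_empty"]], , , ] <- recorded[, ch_of[["red_empty"]], , , ] +
      optics$leakthrough_lf_true * recorded[, ch_of[["eGFP"]], , , ]
    offs <- rep(optics$background_offset, length.out = length(SKIN_CHANNELS))
    for (ch in seq_along(SKIN_CHANNELS))
      recorded[, ch, , , ] <- recorded[, ch, , , ] + offs[ch]
    recorded <- apply_noise(recorded, optics)

    label_map <- array(0L, c(nz, ny, nx))
    for (i in seq_len(n_cells)) {
      pl <- matrix(label_map[z_pre[i], , ], ny, nx)
      pl[cell_idx_full[[i]]] <- i
      label_map[z_pre[i], , ] <- pl
    }

    stack <- image_stack(recorded, channel_names = SKIN_CHANNELS,
                         pixel_size_um = config$pixel_size_um,
                         z_step_um = config$z_step_um, time_points_h = time_h)
    truth <- structure(list(
      cells = data.frame(
        id = seq_len(n_cells), outcome = "eGFP", recomb_time_h = 0,
        x_px = pts$cx, y_px = pts$cy, z_index = z_pre, layer = "basal",
        z_index_post = z_post, layer_post = "dermis",
        brightness_total = brightness_total,
        stringsAsFactors = FALSE),
      label_map = label_map,
      clean = if (store_clean) clean,
      channel_names = SKIN_CHANNELS,
      layers = layers,
      shg_peak_z = band_z[which.max(band_w)],
      relocation_day = relocation_day,
      config = config, condition = "light_dox",
      rois = default_scene_rois(config)
    ), class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}
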
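#' Normalized recombination read-out for 2D time-lapse cultures
#'
#' Per timepoint, integrates a channel's intensity over the segmented
#' region (the area covered by cells, or by marker-positive nuclei) and
#' divides by that region's area in um^2, yielding the per-area intensity
#' used to estimate recombination at each timepoint. A zero-area mask
#' gives value 0 with a warning flag rather than an error.
#'
#' @param corrected A (background-subtracted, leak-through-corrected)
#'   [image_stack()].
#' @param masks A logical (Y, X) matrix applied at every timepoint, or a
#'   list of per-timepoint masks.
#' @param channel Channel name to integrate.
#' @param mode Normalizer semantics: `"cell_area"` / `"rfp_nuclei"`
#'   (intensity / mask area in um^2) or `"roi"` (intensity summed over
#'   the mask and divided by the number of z-planes; used for
#'   ROI-normalized read-outs).
#' @param region,condition Labels copied to the output.
#' @return A `recombination_curve` data frame: region, condition,
#'   timepoint_h, fluorophore, value, normalizer_kind, zero_area flag.
#' @export
quantify_timelapse_2d <- function(corrected, masks, channel,
                                  mode = c("cell_area", "rfp_nuclei", "roi"),
                                  region = "field", condition = NA_character_) {
  mode <- match.arg(mode)
  d <- dim(corrected$pixels)
  nt <- d[1]; nz <- d[3]
  if (is.matrix(masks)) masks <- rep(list(masks), nt)
  if (length(masks) != nt) stopf("need one mask per timepoint (%d != %d)", length(masks), nt)
  ch <- channel_index(corrected, channel)
  px_area <- corrected$pixel_size_um^2
  vals <- numeric(nt); zero <- logical(nt)
  for (t in seq_len(nt)) {
    m <- masks[[t]]
    if (!all(dim(m) == d[4:5])) stopf("mask at timepoint %d does not match image size", t)
    tot <- sum(unlist(lapply(seq_len(nz), function(z)
      sum(matrix(corrected$pixels[t, ch, z, , ], d[4], d[5])[m]))))
    if (mode == "roi") {
      vals[t] <- tot / nz
    } else {
      area <- sum(m) * px_area
      if (area == 0) {
        warnf("zero-area mask at timepoint %d; value set to 0", t)
        vals[t] <- 0; zero[t] <- TRUE
      } else vals[t] <- tot / area
    }
  }
  nk <- switch(mode, cell_area = "cell_area", rfp_nuclei = "cell_area", roi = "roi")
  structure(data.frame(region = region, condition = condition,
                       timepoint_h = corrected$time_points_h,
                       fluorophore = channel, value = vals,
                       normalizer_kind = nk, zero_area = zero,
                       stringsAsFactors = FALSE),
            class = c("recombination_curve", "data.frame"))
}

#' Organoid-normalized recombination read-out
#'
#' Per timepoint and fluorophore, sums the integrated intensity of
#' gate-passing particles and divides by the organoid size (the projected
#' 2D area of the brightfield-classified organoid mask, in um^2).
#'
#' @param corrected A corrected [image_stack()].
#' @param particles A `particle_table` (rows for all fluorophores and
#'   timepoints, with `gate_pass`, `channel`, `timepoint`,
#'   `total_intensity` filled in).
#' @param organoid_masks Logical (Y, X) matrix or per-timepoint list of
#'   the organoid (whole-object) mask.
#' @param fluorophores Channels to report (default: the four reporter
#'   outcomes present in the table).
#' @param region,condition Labels copied to the output.
#' @return A `recombination_curve` data frame.
#' @export
quantify_organoid <- function(corrected, particles, organoid_masks,
                              fluorophores = NULL,
                              region = "organoid", condition = NA_character_) {
  d <- dim(corrected$pixels)
  nt <- d[1]
  if (is.matrix(organoid_masks)) organoid_masks <- rep(list(organoid_masks), nt)
  areas <- vapply(organoid_masks, function(m) sum(m) * corrected$pixel_size_um^2, 0)
  if (any(areas == 0)) stopf("organoid mask is empty at timepoint(s) %s",
                             paste(which(areas == 0), collapse = ", "))
  fluorophores <- fluorophores %||% unique(particles$channel)
  out <- do.call(rbind, lapply(fluorophores, function(fl) {
    vals <- vapply(seq_len(nt), function(t) {
      sel <- particles$channel == fl & particles$timepoint == t &
        !is.na(particles$gate_pass) & particles$gate_pass
      sum(particles$total_intensity[sel]) / areas[t]
    }, 0)
    data.frame(region = region, condition = condition,
               timepoint_h = corrected$time_points_h, fluorophore = fl,
               value = vals, normalizer_kind = "organoid_area",
               zero_area = FALSE, stringsAsFactors = FALSE)
  }))
  structure(out, class = c("recombination_curve", "data.frame"))
}

#' z-stack recombination read-out normalized by the number of z-steps
#'
#' Per timepoint, computes the channel total inside an ROI on each
#' z-plane, sums over planes and divides by the number of z-steps — the
#' depth-normalized read-out used for intravital z-stack time courses.
#'
#' @param corrected A corrected [image_stack()].
#' @param roi An `roi` (or precomputed logical (Y, X) mask).
#' @param channel Channel to integrate.
#' @param region,condition Labels copied to the output.
#' @return A `recombination_curve` data frame with
#'   `normalizer_kind = "n_zsteps"`.
#' @export
quantify_zstack <- function(corrected, roi, channel,
                            region = NULL, condition = NA_character_) {
  d <- dim(corrected$pixels)
  mask <- if (is.matrix(roi)) roi else rasterize_roi(roi, c(d[4], d[5]))
  region <- region %||% (if (inherits(roi, "roi")) roi$label else "roi")
  ch <- channel_index(corrected, channel)
  nt <- d[1]; nz <- d[3]
  vals <- vapply(seq_len(nt), function(t) {
    sum(unlist(lapply(seq_len(nz), function(z)
      sum(matrix(corrected$pixels[t, ch, z, , ], d[4], d[5])[mask])))) / nz
  }, 0)
  structure(data.frame(region = region, condition = condition,
                       timepoint_h = corrected$time_points_h,
                       fluorophore = channel, value = vals,
                       normalizer_kind = "n_zsteps", zero_area = FALSE,
                       stringsAsFactors = FALSE),
            class = c("recombination_curve", "data.frame"))
}

#' Depth profile of reporter vs. collagen signal
#'
#' For each photoconverted ROI, computes the total reporter (eGFP) and
#' fibrillar-collagen (SHG) intensity at each z-plane — raw totals,
#' without segmentation — then the mean and standard error across ROIs
#' per plane. Used to localize cells relative to tissue layers.
#'
#' @param corrected A corrected [image_stack()].
#' @param rois An [roi_set()] with >= 1 `photoconverted` ROI.
#' @param egfp,shg Channel names.
#' @param timepoint Timepoint index.
#' @return A list of class `z_profile`: `per_roi` (long data frame: roi,
#'   z_index, z_um, egfp_total, shg_total), `summary` (z_index, z_um,
#'   egfp_mean, egfp_sem, shg_mean, shg_sem; SEM is `NA` with a single
#'   ROI), `timepoint`.
#' @export
z_profile <- function(corrected, rois, egfp = "eGFP", shg = "SHG", timepoint = 1L) {
  d <- dim(corrected$pixels)
  if (!(shg %in% corrected$channel_names)) stopf("SHG channel '%s' absent from stack", shg)
  ce <- channel_index(corrected, egfp); cs <- channel_index(corrected, shg)
  pc <- rois_by_role(rois, "photoconverted")
  if (length(pc) == 0L) stopf("need at least one photoconverted ROI")
  nz <- d[3]
  per <- do.call(rbind, lapply(pc, function(r) {
    mask <- rasterize_roi(r, c(d[4], d[5]))
    data.frame(roi = r$label, z_index = seq_len(nz),
               z_um = (seq_len(nz) - 1) * corrected$z_step_um,
               egfp_total = vapply(seq_len(nz), function(z)
                 sum(matrix(corrected$pixels[timepoint, ce, z, , ], d[4], d[5])[mask]), 0),
               shg_total = vapply(seq_len(nz), function(z)
                 sum(matrix(corrected$pixels[timepoint, cs, z, , ], d[4], d[5])[mask]), 0),
               stringsAsFactors = FALSE)
  }))
  n_roi <- length(pc)
  sem <- function(x) if (n_roi >= 2L) stats::sd(x) / sqrt(n_roi) else NA_real_
  agg <- do.call(rbind, lapply(seq_len(nz), function(z) {
    sel <- per$z_index == z
    data.frame(z_index = z, z_um = (z - 1) * corrected$z_step_um,
               egfp_mean = mean(per$egfp_total[sel]), egfp_sem = sem(per$egfp_total[sel]),
               shg_mean = mean(per$shg_total[sel]), shg_sem = sem(per$shg_total[sel]))
  }))
  structure(list(per_roi = per, summary = agg, timepoint = timepoint,
                 n_rois = n_roi), class = "z_profile")
}

#' Relocation statistic: eGFP depth centroid relative to the collagen peak
#'
#' Convenience summary (analysis plumbing, not a published read-out): the
#' intensity-weighted eGFP z-centroid minus the z position of the SHG
#' peak, in um. Negative values place the reporter cells above (shallower
#' than) the collagen band; positive values below it.
#'
#' @param profile A [z_profile()] result.
#' @return A single number (um).
#' @export
z_centroid_shift <- function(profile) {
  s <- profile$summary
  w <- s$egfp_mean
  if (sum(w) <= 0) return(NA_real_)
  centroid <- sum(s$z_um * w) / sum(w)
  centroid - s$z_um[which.max(s$shg_mean)]
}

#' Estimate the light-induced hazard multiplier from measured curves
#'
#' Fits first-order recombination kinetics
#' `y(t) = plateau * (1 - exp(-h * t))` jointly to illuminated and
#' control normalized-intensity curves (shared plateau, per-condition
#' hazard h) by least squares, and returns the hazard ratio
#' `h_light / h_control` — the scale on which a light-induced hazard
#' multiplier is defined and recoverable even when the illuminated
#' condition saturates. Raw intensity ratios underestimate the multiplier
#' once a substantial fraction of cells has recombined.
#'
#' @param time_h Numeric vector of timepoints (hours).
#' @param light Matrix or vector of illuminated-condition values
#'   (replicates in rows).
#' @param control Matrix or vector of control-condition values.
#' @return List: `multiplier` (hazard ratio), `hazard_light`,
#'   `hazard_control`, `plateau`.
#' @export
estimate_hazard_multiplier <- function(time_h, light, control) {
  light <- rbind(light); control <- rbind(control)
  yl <- colMeans(light); yc <- colMeans(control)
  if (ncol(light) != length(time_h) || ncol(control) != length(time_h))
    stopf("curves and time grid have different lengths")
  obj <- function(par) {
    a <- exp(par[1]); hl <- exp(par[2]); hc <- exp(par[3])
    sum((yl - a * (1 - exp(-hl * time_h)))^2) +
      sum((yc - a * (1 - exp(-hc * time_h)))^2)
  }
  a0 <- max(yl, 1e-9)
  idx63 <- which(yl > 0.63 * a0)
  t63 <- if (length(idx63)) max(time_h[idx63[1]], max(time_h) / 50) else max(time_h)
  hl0 <- 1 / t63
  hc0 <- max(-log(pmax(1e-6, 1 - yc[length(yc)] / a0)) / max(time_h), 1e-5)
  fit <- stats::optim(log(c(a0, hl0, hc0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- exp(fit$par)
  list(multiplier = p[2] / p[3], hazard_light = p[2], hazard_control = p[3],
       plateau = p[1])
}

#' Write a tidy curve CSV
#'
#' @param curves One `recombination_curve` data frame or a list of them
#'   (rows are concatenated).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  if (!is.data.frame(curves)) curves <- do.call(rbind, curves)
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
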
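# independent oracles used across tests; kept deliberately naive

# brute-force flood-fill connected-component labeling (queue-based BFS)
flood_fill_label <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  k <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- k
    while (nrow(queue) > 0L) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in seq_len(nrow(nb))) {
        yi <- p[1] + nb[d, 1]; xi <- p[2] + nb[d, 2]
        if (yi >= 1 && yi <= ny && xi >= 1 && xi <= nx &&
            mask[yi, xi] && lab[yi, xi] == 0L) {
          lab[yi, xi] <- k
          queue <- rbind(queue, c(yi, xi))
        }
      }
    }
  }
  lab
}

# rasterize a disc of radius r (px) by the pixel-center rule
make_disc <- function(r, size = 2 * r + 5, cx = size / 2, cy = size / 2) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) for (j in seq_len(size))
    m[i, j] <- (i - 0.5 - cy)^2 + (j - 0.5 - cx)^2 <= r^2
  m
}

# rasterize an axis-aligned ellipse with semi-axes a, b
make_ellipse <- function(a, b, size = 2 * ceiling(max(a, b)) + 5) {
  m <- matrix(FALSE, size, size)
  c0 <- size / 2
  for (i in seq_len(size)) for (j in seq_len(size))
    m[i, j] <- ((j - 0.5 - c0) / a)^2 + ((i - 0.5 - c0) / b)^2 <= 1
  m
}

# group-effect F via R's own least-squares machinery (independent of the
# package's sums-of-squares implementation)
lm_f_group <- function(values, group) {
  n <- nrow(values); tt <- ncol(values)
  df <- data.frame(y = as.vector(t(values)),
                   g = factor(rep(group, each = tt)),
                   t = factor(rep(seq_len(tt), times = n)))
  fit <- if (tt > 1L) stats::lm(y ~ g + t, data = df) else stats::lm(y ~ g, data = df)
  stats::anova(fit)["g", "F value"]
}

# small noise-free culture scene shared by several tests
quick_scene <- function(seed = 1, n_timepoints = 2, lf = 0, offset = 0,
                        n_cells = 40, condition = "light_dox",
                        hazard = 0.05, mult = 20, frame_interval_h = 12,
                        optics = NULL, geometry = "culture2d", n_z = 1,
                        rois = NULL) {
  cfg <- scene_config(geometry, field_size_um = c(256, 256), pixel_size_um = 2,
                      n_z = n_z, n_timepoints = n_timepoints,
                      frame_interval_h = frame_interval_h, seed = seed)
  simulate_scene(cfg,
                 recombination_model(background_hazard_per_h = hazard,
                                     light_hazard_multiplier = mult),
                 optics %||% optics_noise_free(leakthrough_lf_true = lf,
                                               background_offset = offset),
                 rois = rois, condition = condition, n_cells = n_cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
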
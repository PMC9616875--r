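#' Regions of interest
#'
#' An ROI is a simple (non-self-intersecting) polygon in pixel coordinates
#' with a role drawn from a closed vocabulary: `photoconverted` (received
#' activating 405 nm light), `control` (matched unilluminated region),
#' `reference` (single-fluorophore region used to estimate spectral
#' leak-through), `background` (cell-free region used for background
#' subtraction) and `organoid` (whole-object outline). Vertices are in
#' pixel units on the 0-based half-open grid: the axis-aligned rectangle
#' (0,0)-(10,10) covers exactly 100 pixels of size 1.
#'
#' @param label Character label, unique within a set.
#' @param role One of `photoconverted`, `control`, `reference`,
#'   `background`, `organoid`.
#' @param vertices Numeric n x 2 matrix of (x, y) polygon vertices in pixel
#'   units; at least 3 rows, not closed (last vertex != first).
#' @param z_range Optional length-2 integer range of applicable z-slices
#'   (1-based, inclusive); `NULL` means all.
#' @param timepoints Optional integer vector of applicable timepoints;
#'   `NULL` means all.
#' @return An object of class `roi`.
#' @export
roi <- function(label, role, vertices, z_range = NULL, timepoints = NULL) {
  roles <- c("photoconverted", "control", "reference", "background", "organoid")
  role <- match.arg(role, roles)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stopf("`vertices` must be an n x 2 numeric matrix")
  if (nrow(vertices) < 3L) stopf("degenerate polygon: %d vertices (< 3)", nrow(vertices))
  if (all(vertices[1, ] == vertices[nrow(vertices), ]) && nrow(vertices) > 3L)
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  if (polygon_self_intersects(vertices))
    stopf("polygon '%s' is self-intersecting; ROIs must be simple polygons", label)
  structure(list(label = as.character(label), role = role,
                 vertices = unname(vertices),
                 z_range = if (!is.null(z_range)) as.integer(z_range),
                 timepoints = if (!is.null(timepoints)) as.integer(timepoints)),
            class = "roi")
}

#' Construct a rectangular ROI
#' @inheritParams roi
#' @param x0,y0 Upper-left corner in pixel units.
#' @param width,height Extent in pixels.
#' @return An `roi`.
#' @export
roi_rect <- function(label, role, x0, y0, width, height, z_range = NULL, timepoints = NULL) {
  v <- rbind(c(x0, y0), c(x0 + width, y0), c(x0 + width, y0 + height), c(x0, y0 + height))
  roi(label, role, v, z_range = z_range, timepoints = timepoints)
}

#' Bundle ROIs into a set
#'
#' @param ... `roi` objects (or a single list of them).
#' @return An object of class `roi_set` (a named list of ROIs).
#' @export
roi_set <- function(...) {
  rois <- list(...)
  if (length(rois) == 1L && !inherits(rois[[1]], "roi")) rois <- rois[[1]]
  if (!all(vapply(rois, inherits, TRUE, "roi"))) stopf("all elements must be `roi` objects")
  labs <- vapply(rois, `[[`, "", "label")
  if (anyDuplicated(labs)) stopf("duplicate ROI labels: %s",
                                 paste(unique(labs[duplicated(labs)]), collapse = ", "))
  nbg <- sum(vapply(rois, `[[`, "", "role") == "background")
  if (nbg > 1L) stopf("at most one background ROI per field is allowed (got %d)", nbg)
  names(rois) <- labs
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs\n", length(x)))
  for (r in x) cat(sprintf("  %-12s %-14s %d vertices\n", r$label, r$role, nrow(r$vertices)))
  invisible(x)
}

#' Select ROIs by role
#' @param rois An `roi_set`.
#' @param role Role to select.
#' @return A list of matching `roi` objects (possibly empty).
#' @export
rois_by_role <- function(rois, role) {
  rois[vapply(rois, `[[`, "", "role") == role]
}

# segment-intersection test over all non-adjacent edge pairs (n is small)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (j == i + 1L || (i == 1L && j == n)) next
    p <- seg[i, ]; q <- seg[j, ]
    d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
    d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
    d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
    d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  }
  FALSE
}

#' Rasterize an ROI to a boolean mask
#'
#' A pixel is included iff its center lies inside the polygon under the
#' even-odd (crossing-number) rule. Pixel (row i, col j) (1-based array
#' indices) has center at x = j - 0.5, y = i - 0.5 in ROI coordinates.
#' Vertices falling outside the image are clipped to the field with a
#' warning.
#'
#' @param roi An `roi`.
#' @param dim_yx Length-2 integer (Y, X) image dimensions, or an
#'   `image_stack` from which they are taken.
#' @return A logical (Y, X) matrix.
#' @export
rasterize_roi <- function(roi, dim_yx) {
  if (inherits(dim_yx, "image_stack")) dim_yx <- dim(dim_yx$pixels)[4:5]
  ny <- dim_yx[1]; nx <- dim_yx[2]
  v <- roi$vertices
  if (nrow(v) < 3L) stopf("degenerate polygon (< 3 vertices)")
  if (any(v[, 1] < 0 | v[, 1] > nx | v[, 2] < 0 | v[, 2] > ny)) {
    warnf("ROI '%s' extends outside the %dx%d field; clipping vertices", roi$label, ny, nx)
    v[, 1] <- pmin(pmax(v[, 1], 0), nx)
    v[, 2] <- pmin(pmax(v[, 2], 0), ny)
  }
  cx <- rep(seq_len(nx) - 0.5, each = ny)   # column-major order matches matrix()
  cy <- rep(seq_len(ny) - 0.5, times = nx)
  inside <- point_in_polygon(cx, cy, v)
  matrix(inside, ny, nx)
}

# vectorized even-odd rule; points exactly on an edge count by ray crossing
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write an ROI set to JSON
#' @param rois An `roi_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  out <- lapply(unname(rois), function(r) {
    list(label = r$label, role = r$role,
         vertices = apply(r$vertices, 1, as.numeric, simplify = FALSE),
         z_range = r$z_range, timepoints = r$timepoints)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an ROI set from JSON
#' @param path Path written by [write_roi_json()].
#' @return An `roi_set`.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path)
  roi_set(lapply(raw, function(r) {
    roi(r$label, r$role, do.call(rbind, lapply(r$vertices, unlist)),
        z_range = if (!is.null(r$z_range)) unlist(r$z_range),
        timepoints = if (!is.null(r$timepoints)) unlist(r$timepoints))
  }))
}

#' Auto-place a control ROI away from photoconverted regions
#'
#' Places a control rectangle congruent to the given photoconverted ROI at
#' least `min_distance_um` (default 150) from every photoconverted ROI,
#' mirroring the matched-control convention for photoactivation
#' experiments. Searches a coarse grid and returns the admissible position
#' farthest from all photoconverted ROIs.
#'
#' @param rois An `roi_set` containing >= 1 photoconverted ROI.
#' @param dim_yx (Y, X) field dimensions in pixels or an `image_stack`.
#' @param pixel_size_um Pixel size, to express the distance floor in pixels.
#' @param min_distance_um Minimum center-to-boundary distance in um.
#' @param label Label for the new ROI.
#' @return An `roi` with role `control`.
#' @export
auto_control_roi <- function(rois, dim_yx, pixel_size_um = 1,
                             min_distance_um = 150, label = "control_auto") {
  if (inherits(dim_yx, "image_stack")) {
    pixel_size_um <- dim_yx$pixel_size_um
    dim_yx <- dim(dim_yx$pixels)[4:5]
  }
  pc <- rois_by_role(rois, "photoconverted")
  if (length(pc) == 0L) stopf("no photoconverted ROI to mirror")
  v0 <- pc[[1]]$vertices
  w <- diff(range(v0[, 1])); h <- diff(range(v0[, 2]))
  ny <- dim_yx[1]; nx <- dim_yx[2]
  min_px <- min_distance_um / pixel_size_um
  centers <- do.call(rbind, lapply(pc, function(r) colMeans(r$vertices)))
  gx <- seq(w / 2, nx - w / 2, length.out = 25)
  gy <- seq(h / 2, ny - h / 2, length.out = 25)
  best <- NULL; best_d <- -Inf
  for (x in gx) for (y in gy) {
    d <- min(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2))
    if (d > best_d) { best_d <- d; best <- c(x, y) }
  }
  if (best_d < min_px + sqrt((w / 2)^2 + (h / 2)^2))
    warnf("field too small to place a control %g um from photoconverted regions (achieved %g um)",
          min_distance_um, (best_d - sqrt((w / 2)^2 + (h / 2)^2)) * pixel_size_um)
  roi_rect(label, "control", best[1] - w / 2, best[2] - h / 2, w, h)
}
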
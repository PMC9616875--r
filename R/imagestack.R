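#' Calibrated multichannel image stack
#'
#' The package's single image container: a 5-axis array in fixed axis order
#' T (time) x C (channel) x Z (slice) x Y (row) x X (column), together with
#' its physical calibration. Pixel indices are 0-based half-open in the
#' coordinate conventions used by ROIs: pixel (x, y) covers
#' `[x, x+1) x [y, y+1)` and has its center at `(x + 0.5, y + 0.5)`; y
#' increases downward. All physical quantities are in micrometers and hours.
#'
#' @param pixels Numeric array. Arrays with fewer than 5 dimensions are
#'   promoted on the left: a `(Y, X)` matrix becomes `(1, 1, 1, Y, X)`, a
#'   `(Z, Y, X)` array `(1, 1, Z, Y, X)`, and a `(C, Z, Y, X)` array
#'   `(1, C, Z, Y, X)`. Values must be finite and nonnegative.
#' @param channel_names Character vector, one name per channel.
#' @param pixel_size_um Lateral pixel size in micrometers.
#' @param z_step_um Axial step between z-slices in micrometers.
#' @param time_points_h Nondecreasing numeric vector of acquisition times in
#'   hours, one per timepoint. Defaults to `0:(T-1)`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channel_names = NULL, pixel_size_um = 1,
                        z_step_um = 1, time_points_h = NULL) {
  if (!is.numeric(pixels)) stopf("`pixels` must be a numeric array")
  d <- dim(pixels) %||% length(pixels)
  if (length(d) > 5L) stopf("`pixels` has %d axes; at most 5 (T,C,Z,Y,X) supported", length(d))
  if (length(d) < 2L) stopf("`pixels` must have at least Y and X axes")
  dim(pixels) <- c(rep(1L, 5L - length(d)), d)
  if (any(!is.finite(pixels))) stopf("pixel values must be finite")
  if (any(pixels < 0)) stopf("pixel values must be >= 0")
  nt <- dim(pixels)[1]; nc <- dim(pixels)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stopf("length(channel_names) = %d but stack has %d channels", length(channel_names), nc)
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(z_step_um, "z_step_um")
  if (is.null(time_points_h)) time_points_h <- as.numeric(seq_len(nt) - 1L)
  if (length(time_points_h) != nt)
    stopf("length(time_points_h) = %d but stack has %d timepoints", length(time_points_h), nt)
  if (is.unsorted(time_points_h)) stopf("`time_points_h` must be nondecreasing")
  structure(list(
    pixels = pixels,
    channel_names = as.character(channel_names),
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    time_points_h = as.numeric(time_points_h)
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> T=%d C=%d Z=%d Y=%d X=%d\n", d[1], d[2], d[3], d[4], d[5]))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  pixel %g um, z-step %g um, t = %s h\n", x$pixel_size_um, x$z_step_um,
              paste(signif(range(x$time_points_h), 4), collapse = "..")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' Look up a channel index by name
#' @param stack An `image_stack`.
#' @param channel Channel name or integer index.
#' @return Integer channel index.
#' @export
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(stack$channel_names)) stopf("channel index %d out of range", ch)
    return(ch)
  }
  ch <- match(channel, stack$channel_names)
  if (is.na(ch))
    stopf("channel '%s' not found (have: %s)", channel,
          paste(stack$channel_names, collapse = ", "))
  ch
}

#' Extract a single (Y, X) plane
#' @param stack An `image_stack`.
#' @param t,z Timepoint and z-slice indices (1-based).
#' @param channel Channel name or index.
#' @return A numeric (Y, X) matrix.
#' @export
get_plane <- function(stack, t = 1L, channel = 1L, z = 1L) {
  ch <- channel_index(stack, channel)
  d <- dim(stack$pixels)
  if (t < 1 || t > d[1]) stopf("timepoint %d out of range", t)
  if (z < 1 || z > d[3]) stopf("z index %d out of range", z)
  matrix(stack$pixels[t, ch, z, , ], d[4], d[5])
}

#' Replace a single (Y, X) plane
#' @inheritParams get_plane
#' @param value Numeric (Y, X) matrix.
#' @return The modified stack (invisibly usable in pipelines).
#' @export
set_plane <- function(stack, t = 1L, channel = 1L, z = 1L, value) {
  ch <- channel_index(stack, channel)
  d <- dim(stack$pixels)
  if (!all(dim(value) == d[4:5])) stopf("plane dimensions do not match stack")
  stack$pixels[t, ch, z, , ] <- value
  stack
}
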
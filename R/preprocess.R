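#' Background subtraction from a cell-free region
#'
#' For each channel and timepoint, subtracts the mean (or median) signal
#' measured inside the background ROI — an area without cells — from every
#' pixel of every z-plane, clipping at zero. Alternatively a fixed
#' per-channel scalar background can be supplied. The subtracted values
#' are recorded on the result for provenance.
#'
#' @param stack An [image_stack()].
#' @param rois An [roi_set()] containing one `background` ROI (ignored if
#'   `background` is given).
#' @param background Optional per-channel numeric vector (recycled) of
#'   fixed background values.
#' @param stat `"mean"` (default) or `"median"`.
#' @return A `corrected_stack`: an `image_stack` with attributes
#'   `background_values` (T x C matrix) and `leakthrough_applied` (list).
#' @export
subtract_background <- function(stack, rois = NULL, background = NULL,
                                stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!inherits(stack, "image_stack")) stopf("`stack` must be an image_stack")
  d <- dim(stack$pixels)
  nt <- d[1]; nc <- d[2]; nz <- d[3]
  bgmat <- matrix(0, nt, nc, dimnames = list(NULL, stack$channel_names))
  if (!is.null(background)) {
    bgmat[] <- rep(rep(background, length.out = nc), each = nt)
  } else {
    if (is.null(rois)) stopf("either `rois` (with a background ROI) or `background` is required")
    bg <- rois_by_role(rois, "background")
    if (length(bg) == 0L) stopf("no background ROI in the ROI set")
    mask <- rasterize_roi(bg[[1]], c(d[4], d[5]))
    if (!any(mask)) stopf("background ROI is empty after rasterization")
    fn <- if (stat == "mean") mean else stats::median
    for (t in seq_len(nt)) for (ch in seq_len(nc)) {
      vals <- unlist(lapply(seq_len(nz), function(z)
        matrix(stack$pixels[t, ch, z, , ], d[4], d[5])[mask]))
      bgmat[t, ch] <- fn(vals)
    }
  }
  out <- stack
  for (t in seq_len(nt)) for (ch in seq_len(nc))
    out$pixels[t, ch, , , ] <- pmax(0, out$pixels[t, ch, , , ] - bgmat[t, ch])
  attr(out, "background_values") <- bgmat
  attr(out, "leakthrough_applied") <- attr(stack, "leakthrough_applied") %||% list()
  class(out) <- c("corrected_stack", class(stack))
  out
}

#' Estimate a spectral leak-through factor
#'
#' Estimates the mixing coefficient LF of a source fluorophore into a
#' target detection channel by dividing the target by the source
#' background-subtracted totals inside a reference region containing
#' source-only signal: `LF = sum(target_bs) / sum(source_bs)` (the ratio
#' of sums, i.e. of means — robust to near-zero denominators), clamped at
#' 0. The estimate is made once, at a designated timepoint, and applied
#' globally: leak-through is an optical constant of the channel pair.
#'
#' When given a raw stack plus a background ROI (or `background`
#' values), the background is subtracted from the ROI *totals*
#' (`sum(raw) - n_px * bg`) rather than from clipped pixels: clipping
#' near-zero pixels at 0 before summing would bias the ratio upward in
#' sparse reference regions. A stack that is already background-subtracted
#' ([subtract_background()]) is used as-is.
#'
#' @param stack_bs A raw [image_stack()] (then supply `rois` with a
#'   background ROI, or `background`) or a background-subtracted
#'   `corrected_stack`.
#' @param source,target Channel names (e.g. `"nGFP"`, `"cYFP"`).
#' @param reference_roi An `roi`, or the label of a `reference` ROI
#'   present in `rois`.
#' @param rois Optional [roi_set()] used to resolve `reference_roi` by
#'   label; defaults to its single `reference` ROI if omitted.
#' @param timepoint Timepoint index at which to estimate (default 1).
#' @param floor Minimum mean source signal per reference pixel; below it
#'   the reference region is uninformative and an error is raised.
#' @param background Optional per-channel fixed background values for the
#'   raw-stack path.
#' @return A `leakthrough_model` list: `source_channel`, `target_channel`,
#'   `LF`, `reference_roi_label`, `estimated_at_timepoint`.
#' @export
estimate_leakthrough <- function(stack_bs, source, target, reference_roi = NULL,
                                 rois = NULL, timepoint = 1L, floor = 1e-3,
                                 background = NULL) {
  if (identical(source, target)) stopf("source and target channels must differ")
  cs <- channel_index(stack_bs, source)
  ct <- channel_index(stack_bs, target)
  if (is.null(reference_roi)) {
    if (is.null(rois)) stopf("supply `reference_roi` or an `rois` set with a reference ROI")
    rr <- rois_by_role(rois, "reference")
    if (length(rr) == 0L) stopf("no reference ROI in the ROI set")
    reference_roi <- rr[[1]]
  } else if (is.character(reference_roi)) {
    if (is.null(rois) || is.null(rois[[reference_roi]]))
      stopf("reference ROI '%s' not found in `rois`", reference_roi)
    reference_roi <- rois[[reference_roi]]
  }
  d <- dim(stack_bs$pixels)
  mask <- rasterize_roi(reference_roi, c(d[4], d[5]))
  if (!any(mask)) stopf("reference ROI is empty after rasterization")
  n_px <- sum(mask) * d[3]
  bg <- c(0, 0)  # source, target
  if (!inherits(stack_bs, "corrected_stack")) {
    if (!is.null(background)) {
      bgv <- rep(background, length.out = d[2])
      bg <- bgv[c(cs, ct)]
    } else if (!is.null(rois) && length(rois_by_role(rois, "background")) > 0L) {
      bmask <- rasterize_roi(rois_by_role(rois, "background")[[1]], c(d[4], d[5]))
      if (any(bmask)) {
        bg <- vapply(c(cs, ct), function(ch) mean(unlist(lapply(seq_len(d[3]), function(z)
          matrix(stack_bs$pixels[timepoint, ch, z, , ], d[4], d[5])[bmask]))), 0)
      }
    }
  }
  src_sum <- sum(unlist(lapply(seq_len(d[3]), function(z)
    matrix(stack_bs$pixels[timepoint, cs, z, , ], d[4], d[5])[mask]))) - n_px * bg[1]
  tgt_sum <- sum(unlist(lapply(seq_len(d[3]), function(z)
    matrix(stack_bs$pixels[timepoint, ct, z, , ], d[4], d[5])[mask]))) - n_px * bg[2]
  if (src_sum / n_px < floor)
    stopf("reference region uninformative: mean %s signal %.4g below floor %.4g",
          source, src_sum / n_px, floor)
  structure(list(source_channel = stack_bs$channel_names[cs],
                 target_channel = stack_bs$channel_names[ct],
                 LF = max(0, tgt_sum / src_sum),
                 reference_roi_label = reference_roi$label,
                 estimated_at_timepoint = as.integer(timepoint)),
            class = "leakthrough_model")
}

#' @export
print.leakthrough_model <- function(x, ...) {
  cat(sprintf("<leakthrough_model> %s -> %s: LF = %.6g (ref '%s', t = %d)\n",
              x$source_channel, x$target_channel, x$LF,
              x$reference_roi_label, x$estimated_at_timepoint))
  invisible(x)
}

#' Apply a leak-through correction
#'
#' Corrects the target channel pixelwise as
#' `target := max(0, target_bs - source_bs * LF)` at all timepoints and
#' z-planes, where both channels are background-subtracted.
#'
#' @param stack_bs A background-subtracted stack.
#' @param model A `leakthrough_model` from [estimate_leakthrough()], or a
#'   numeric LF value (then `source`/`target` must be given).
#' @param source,target Channel names when `model` is numeric.
#' @return The corrected stack, with the applied model appended to its
#'   `leakthrough_applied` attribute.
#' @export
correct_leakthrough <- function(stack_bs, model, source = NULL, target = NULL) {
  if (is.numeric(model)) {
    if (is.null(source) || is.null(target))
      stopf("`source` and `target` are required when `model` is a numeric LF")
    model <- structure(list(source_channel = source, target_channel = target,
                            LF = model, reference_roi_label = NA_character_,
                            estimated_at_timepoint = NA_integer_),
                       class = "leakthrough_model")
  }
  cs <- channel_index(stack_bs, model$source_channel)
  ct <- channel_index(stack_bs, model$target_channel)
  out <- stack_bs
  out$pixels[, ct, , , ] <- pmax(0, out$pixels[, ct, , , ] -
                                    model$LF * out$pixels[, cs, , , ])
  lk <- attr(out, "leakthrough_applied") %||% list()
  attr(out, "leakthrough_applied") <- c(lk, list(model))
  if (!inherits(out, "corrected_stack")) class(out) <- c("corrected_stack", class(out))
  out
}
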
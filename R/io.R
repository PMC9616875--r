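#' Write a calibrated stack to multipage TIFF with a JSON sidecar
#'
#' Pages are written in T-major, then C, then Z order as 32-bit samples.
#' Because baseline TIFF writers here store samples in `[0, 1]` on a
#' 32-bit grid, pixel values are divided by a power-of-two scale factor
#' covering the data range (recorded in the sidecar and reapplied on
#' read). Integer-valued stacks — photon/ADU counts, the usual case —
#' are flagged in the sidecar and snapped back to integers on read, so
#' they round-trip exactly; continuous values round-trip to about 2e-10
#' of the data range. Axis sizes,
#' channel names, calibration and timepoints go to the `<path>.json`
#' sidecar, the package's stack metadata format; [read_stack()]
#' additionally understands OME-style `ImageDescription` metadata written
#' by acquisition software.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stopf("`stack` must be an image_stack")
  d <- dim(stack$pixels)
  mx <- max(stack$pixels)
  scale <- 2^max(0, ceiling(log2(max(mx, .Machine$double.xmin))))
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[k]] <- matrix(stack$pixels[t, ch, z, , ], d[4], d[5]) / scale
    k <- k + 1L
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  meta <- list(
    axes = "TCZYX",
    shape = as.integer(d),
    channel_names = stack$channel_names,
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    time_points_h = stack$time_points_h,
    intensity_scale = scale,
    integer_data = all(stack$pixels == round(stack$pixels))
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

parse_ome_description <- function(desc) {
  grab <- function(attr) {
    m <- regmatches(desc, regexpr(sprintf('%s="[^"]*"', attr), desc))
    if (length(m) == 0L) return(NA_real_)
    as.numeric(sub('"$', "", sub(sprintf('%s="', attr), "", m)))
  }
  list(SizeX = grab("SizeX"), SizeY = grab("SizeY"), SizeZ = grab("SizeZ"),
       SizeC = grab("SizeC"), SizeT = grab("SizeT"),
       PhysicalSizeX = grab("PhysicalSizeX"), PhysicalSizeZ = grab("PhysicalSizeZ"))
}

#' Read a TIFF / OME-style stack
#'
#' Resolves axes from, in order of precedence: the JSON sidecar written by
#' [write_stack()]; an OME-style `ImageDescription` (SizeT/SizeC/SizeZ);
#' or, for a single-page file, promotion to shape (1, 1, 1, Y, X). A
#' multipage file without axis metadata is ambiguous and is an error.
#' Missing pixel size defaults to 1 um with a warning.
#'
#' @param path TIFF path.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (is.matrix(pages) || (is.array(pages) && !is.list(pages))) pages <- list(pages)
  npage <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  side <- sidecar_path(path)
  meta <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    scale <- meta$intensity_scale %||% 1
  } else {
    desc <- attr(pages[[1]], "description")
    ome <- if (!is.null(desc)) parse_ome_description(desc) else NULL
    if (!is.null(ome) && !is.na(ome$SizeT)) {
      shape <- as.integer(c(ome$SizeT, ome$SizeC, ome$SizeZ, ome$SizeY, ome$SizeX))
      scale <- 1
      meta <- list(pixel_size_um = ome$PhysicalSizeX, z_step_um = ome$PhysicalSizeZ)
    } else if (npage == 1L) {
      shape <- c(1L, 1L, 1L, ny, nx)
      scale <- 1
    } else {
      stopf("cannot resolve T/C/Z axes of multipage TIFF '%s': %d pages and no axis metadata (sidecar or OME description)",
            path, npage)
    }
  }
  if (prod(shape[1:3]) != npage)
    stopf("axis metadata of '%s' declares %d planes but file has %d pages",
          path, prod(shape[1:3]), npage)
  if (shape[4] != ny || shape[5] != nx)
    stopf("axis metadata Y/X (%d x %d) does not match page size (%d x %d)",
          shape[4], shape[5], ny, nx)
  px <- array(0, shape)
  k <- 1L
  for (t in seq_len(shape[1])) for (ch in seq_len(shape[2])) for (z in seq_len(shape[3])) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate multi-sample pages
    pg <- pg * scale
    if (isTRUE(meta$integer_data)) pg <- round(pg)
    px[t, ch, z, , ] <- pg
    k <- k + 1L
  }
  px[px < 0] <- 0
  psz <- meta$pixel_size_um
  if (is.null(psz) || is.na(psz)) {
    warnf("no pixel size metadata in '%s'; defaulting to 1 um", path)
    psz <- 1
  }
  zst <- meta$z_step_um
  if (is.null(zst) || is.na(zst)) zst <- 1
  image_stack(px,
              channel_names = meta$channel_names %||% paste0("ch", seq_len(shape[2])),
              pixel_size_um = psz, z_step_um = zst,
              time_points_h = meta$time_points_h %||% NULL)
}
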
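#' Multi-channel slice images
#'
#' Container for a 2-D multi-channel fluorescence image with named channel
#' roles and pixel calibration. Conventional roles are `SMA` (vascular
#' smooth muscle actin), `MX04` (methoxy-X04 amyloid label), `COLIV`
#' (collagen IV, basement membrane), `GFAP` (astrocytes), `FITC3K` and
#' `TMR40K` (3 kDa FITC and 40 kDa TMR dextran CSF tracers); any subset may
#' be present. Pixel coordinates are (x = column, y = row) with pixel
#' `(r, c)` centered at `(c - 0.5, r - 0.5)`.
#'
#' @param channels Named list of numeric matrices, all the same shape, with
#'   non-negative intensities.
#' @param pixel_size_um Micrometres per pixel.
#' @param slice_id,mouse_id,group Optional labels carried into result tables.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(channels, pixel_size_um, slice_id = "slice",
                          mouse_id = NULL, group = NULL) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  if (anyDuplicated(names(channels))) abort("channel role names must be unique.")
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1)))) {
    abort("each channel must be a numeric matrix.")
  }
  if (length(unique(dims)) != 1) abort("all channels must have the same shape.")
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("channel intensities must be non-negative.")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be positive.")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         slice_id = slice_id, mouse_id = mouse_id, group = group),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_image ", x$slice_id, ": ", d[1], " x ", d[2], " px, ",
      x$pixel_size_um, " um/px, channels: ",
      paste(names(x$channels), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

get_channel <- function(image, role) {
  stopifnot(inherits(image, "channel_image"))
  if (!role %in% names(image$channels)) {
    abort(paste0("unknown channel role `", role, "`; available: ",
                 paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[role]]
}

#' Multi-channel TIFF round trip
#'
#' Channel images are written as multi-page TIFFs (one page per channel,
#' 16-bit) with channel roles and pixel calibration in a YAML sidecar.
#'
#' @param image A [channel_image()] with intensities in `[0, 1]`.
#' @param path TIFF path; sidecar defaults to `<path>.yaml`.
#' @param meta_path Optional explicit sidecar path.
#' @export
write_channel_image <- function(image, path, meta_path = paste0(path, ".yaml")) {
  stopifnot(inherits(image, "channel_image"))
  rng <- range(unlist(lapply(image$channels, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    abort("intensities must lie in [0, 1] for TIFF serialization.")
  }
  tiff::writeTIFF(unname(image$channels), path, bits.per.sample = 16L)
  yaml::write_yaml(list(
    channel_roles = names(image$channels),
    pixel_size_um = image$pixel_size_um,
    slice_id = image$slice_id, mouse_id = image$mouse_id, group = image$group
  ), meta_path)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path, meta_path = paste0(path, ".yaml")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(meta_path)
  channels <- setNames(pages, meta$channel_roles)
  channel_image(channels, meta$pixel_size_um,
                slice_id = meta$slice_id %||% "slice",
                mouse_id = meta$mouse_id, group = meta$group)
}

#' Vessel regions of interest
#'
#' A labelled vessel region, normally drawn as a freehand outline around one
#' vessel. Supply either a logical `mask` matching the image shape or a
#' `polygon` (n x 2 matrix of x, y vertices in pixel coordinates) that is
#' rasterized with the pixel-center rule.
#'
#' @param mask Logical matrix, or `NULL` when a polygon is given.
#' @param polygon n x 2 matrix of vertices, or `NULL`.
#' @param vessel_type `"surface_artery"` or `"penetrating_artery"`.
#' @param id Identifier.
#' @param depth_class Optional `"superficial"` or `"deep"`.
#' @return An object of class `vessel_roi`.
#' @export
vessel_roi <- function(mask = NULL, polygon = NULL,
                       vessel_type = c("surface_artery", "penetrating_artery"),
                       id = "roi", depth_class = NULL) {
  vessel_type <- match.arg(vessel_type)
  if (is.null(mask) && is.null(polygon)) {
    abort("supply `mask` or `polygon`.")
  }
  structure(
    list(mask = mask, polygon = polygon, vessel_type = vessel_type,
         id = id, depth_class = depth_class),
    class = "vessel_roi"
  )
}

roi_mask <- function(roi, dim) {
  m <- if (!is.null(roi$mask)) roi$mask else polygon_mask(roi$polygon, dim)
  if (!identical(dim(m), as.integer(dim))) {
    abort(paste0("ROI `", roi$id, "` does not match the image shape."))
  }
  if (!any(m)) abort(paste0("ROI `", roi$id, "` rasterizes to an empty mask."))
  m
}
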
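#' Line-scan kymograph records
#'
#' A kymograph is the space-by-time intensity record produced by repeatedly
#' scanning a single line set orthogonal to a vessel: rows are positions
#' along the scan line, columns are successive time lines. Wall positions
#' over time encode the diameter dynamics that the pulsatility analysis
#' extracts. Scan lines for pulsatility measurement are conventionally placed
#' on vessels within 150 um of the cortical surface, where the lumen is
#' filled with a bright intravascular dye.
#'
#' @param intensities Numeric matrix, space along the scan line (rows) by
#'   time lines (columns). Lumen must be brighter than background.
#' @param pixel_size_um Spatial calibration, micrometres per pixel.
#' @param line_period_ms Temporal calibration, milliseconds per line.
#' @param vessel_id Identifier carried into result tables.
#' @param vessel_type One of `"surface_artery"`, `"penetrating_artery"`,
#'   `"surface_vein"`, `"ascending_vein"` — the four cerebrovascular tree
#'   positions the analysis distinguishes.
#' @param depth_um Optional imaging depth below the cortical surface.
#' @param annotations Optional named list of extra labels (e.g. `caa`,
#'   `group`, `age`) propagated to batch result tables.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensities, pixel_size_um, line_period_ms,
                      vessel_id = "vessel", vessel_type = "surface_artery",
                      depth_um = NULL, annotations = list()) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix (space x time).")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number.")
  }
  if (!is.numeric(line_period_ms) || line_period_ms <= 0) {
    abort("`line_period_ms` must be a positive number.")
  }
  vessel_type <- match.arg(vessel_type, vessel_types())
  structure(
    list(
      intensities = intensities,
      pixel_size_um = pixel_size_um,
      line_period_ms = line_period_ms,
      vessel_id = vessel_id,
      vessel_type = vessel_type,
      depth_um = depth_um,
      annotations = annotations
    ),
    class = "kymograph"
  )
}

#' @rdname kymograph
#' @export
vessel_types <- function() {
  c("surface_artery", "penetrating_artery", "surface_vein", "ascending_vein")
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph ", x$vessel_id, ": ",
      nrow(x$intensities), " px x ", ncol(x$intensities), " lines, ",
      x$pixel_size_um, " um/px, ", x$line_period_ms, " ms/line, ",
      x$vessel_type, ">\n", sep = "")
  invisible(x)
}

#' Kymograph TIFF round trip
#'
#' Kymographs are stored as single-page TIFF images (space x time) with the
#' acquisition metadata (pixel size, line period, vessel annotations) in a
#' YAML sidecar, since TIFF tags do not carry calibrations portably.
#'
#' @param kymo A [kymograph()] object with intensities in `[0, 1]`.
#' @param path Path of the TIFF file; the YAML sidecar is written next to it
#'   (`<path>.yaml`) unless `meta_path` is given.
#' @param meta_path Optional explicit sidecar path.
#' @return `write_kymograph()` returns `path` invisibly; `read_kymograph()`
#'   returns a [kymograph()].
#' @export
write_kymograph <- function(kymo, path, meta_path = paste0(path, ".yaml")) {
  stopifnot(inherits(kymo, "kymograph"))
  if (any(kymo$intensities < 0 | kymo$intensities > 1)) {
    abort("kymograph intensities must lie in [0, 1] for TIFF serialization.")
  }
  tiff::writeTIFF(kymo$intensities, path, bits.per.sample = 16L)
  meta <- list(
    pixel_size_um = kymo$pixel_size_um,
    line_period_ms = kymo$line_period_ms,
    vessel_id = kymo$vessel_id,
    vessel_type = kymo$vessel_type,
    depth_um = kymo$depth_um,
    annotations = kymo$annotations
  )
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path, meta_path = paste0(path, ".yaml")) {
  img <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(meta_path)
  kymograph(
    intensities = img,
    pixel_size_um = meta$pixel_size_um,
    line_period_ms = meta$line_period_ms,
    vessel_id = meta$vessel_id %||% "vessel",
    vessel_type = meta$vessel_type %||% "surface_artery",
    depth_um = meta$depth_um,
    annotations = meta$annotations %||% list()
  )
}
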
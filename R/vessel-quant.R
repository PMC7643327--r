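#' Vessel wall mask from merged SMA and MX04 channels
#'
#' In CAA, amyloid replaces smooth-muscle coverage on artery walls, so
#' neither channel alone outlines the whole wall: the SMA and MX04 channels
#' are merged (pixel-wise maximum by default, preserving either signal) and
#' thresholded inside the vessel ROI to form the wall mask against which
#' per-channel coverage is measured.
#'
#' @param image A [channel_image()] with `SMA` and `MX04` channels.
#' @param roi A [vessel_roi()].
#' @param policy Threshold policy (see [threshold_policy]); resolved on the
#'   merged intensities inside the ROI.
#' @param merge `"max"` (default) or `"sum"`.
#' @return Logical mask with attributes `threshold` (resolved value),
#'   `policy` and `merge`.
#' @export
vessel_mask <- function(image, roi, policy = threshold_otsu(),
                        merge = c("max", "sum")) {
  merge <- match.arg(merge)
  sma <- get_channel(image, "SMA")
  mx <- get_channel(image, "MX04")
  merged <- if (merge == "max") pmax(sma, mx) else sma + mx
  rm_ <- roi_mask(roi, dim(merged))
  thr <- resolve_threshold(policy, merged[rm_])
  mask <- rm_ & merged > thr
  if (!any(mask)) {
    abort(paste0("vessel mask for ROI `", roi$id,
                 "` is empty at threshold ", signif(thr, 4), "."))
  }
  attr(mask, "threshold") <- thr
  attr(mask, "policy") <- if (inherits(policy, "pvq_threshold")) policy$method else "fixed"
  attr(mask, "merge") <- merge
  mask
}

#' Per-channel coverage of a vessel mask
#'
#' Percentage of mask pixels that are positive in the requested channel:
#' `100 * positive-in-mask / mask-size`. Used for smooth-muscle (SMA) and
#' vascular amyloid (MX04) coverage of artery walls.
#'
#' @param image A [channel_image()].
#' @param mask Logical matrix (e.g. from [vessel_mask()]).
#' @param channel Channel role to measure.
#' @param policy Threshold policy defining "positive"; resolved on the whole
#'   channel so the criterion is comparable across vessels of one image.
#' @return One-row tibble: `channel`, `coverage_pct`, `threshold`,
#'   `n_mask_px`.
#' @export
channel_coverage <- function(image, mask, channel, policy = threshold_otsu()) {
  ch <- get_channel(image, channel)
  if (!is.logical(mask) || !identical(dim(mask), dim(ch))) {
    abort("`mask` must be a logical matrix matching the image shape.")
  }
  if (!any(mask)) abort("`mask` is empty.")
  thr <- resolve_threshold(policy, ch)
  tibble(
    channel = channel,
    coverage_pct = 100 * sum(ch[mask] > thr) / sum(mask),
    threshold = thr,
    n_mask_px = sum(mask)
  )
}

#' Vascular density in a fixed-size square ROI
#'
#' Percentage of a constant-sized square region (default 0.4 mm x 0.4 mm)
#' occupied by collagen-IV-positive pixels — a size-standardized measure of
#' vascular (basement membrane) density.
#'
#' @param image A [channel_image()] containing the density channel.
#' @param center_px Length-2 vector, ROI center in pixel coordinates (x, y).
#' @param roi_size_um Side length of the square ROI, um (default 400).
#' @param channel Channel role (default `"COLIV"`).
#' @param policy Threshold policy; resolved on the ROI pixels.
#' @return One-row tibble: `density_pct`, `threshold`, `roi_px`.
#' @export
vascular_density <- function(image, center_px, roi_size_um = 400,
                             channel = "COLIV", policy = threshold_otsu()) {
  ch <- get_channel(image, channel)
  side_px <- roi_size_um / image$pixel_size_um
  half <- side_px / 2
  cols <- ceiling(center_px[1] - half + 0.5):floor(center_px[1] + half - 0.5 + 1)
  rows <- ceiling(center_px[2] - half + 0.5):floor(center_px[2] + half - 0.5 + 1)
  cols <- cols[cols >= 1]; rows <- rows[rows >= 1]
  if (length(rows) < 1 || length(cols) < 1 ||
      min(center_px - half) < 0 ||
      center_px[1] + half > ncol(ch) || center_px[2] + half > nrow(ch)) {
    abort("density ROI exceeds the image bounds.")
  }
  sub <- ch[rows, cols]
  thr <- resolve_threshold(policy, sub)
  tibble(
    density_pct = 100 * sum(sub > thr) / length(sub),
    threshold = thr,
    roi_px = length(sub)
  )
}

#' Parenchymal plaque coverage
#'
#' Amyloid plaque burden over a brain region: the MX04 channel is
#' background-subtracted, a constant threshold is applied, and the burden is
#' `100 * thresholded MX04 pixels / region size`. The background is the
#' median intensity of the region by default (plaques are sparse, so the
#' median reads the parenchymal background), or of an explicit background
#' mask.
#'
#' @param image A [channel_image()] with an `MX04` channel.
#' @param brain_roi Logical matrix delimiting the region.
#' @param policy Threshold applied to the background-subtracted image; a
#'   fixed value is recommended when comparing across slices.
#' @param background_mask Optional logical matrix for background estimation.
#' @return One-row tibble: `plaque_pct`, `threshold`, `background`,
#'   `roi_px`.
#' @export
plaque_coverage <- function(image, brain_roi, policy = threshold_otsu(),
                            background_mask = NULL) {
  mx <- get_channel(image, "MX04")
  if (!is.logical(brain_roi) || !identical(dim(brain_roi), dim(mx))) {
    abort("`brain_roi` must be a logical matrix matching the image shape.")
  }
  if (!any(brain_roi)) abort("`brain_roi` is empty.")
  bg <- if (is.null(background_mask)) median(mx[brain_roi]) else {
    if (!any(background_mask)) abort("`background_mask` is empty.")
    median(mx[background_mask])
  }
  sub <- mx - bg
  thr <- resolve_threshold(policy, sub[brain_roi])
  tibble(
    plaque_pct = 100 * sum(sub[brain_roi] > thr) / sum(brain_roi),
    threshold = thr,
    background = bg,
    roi_px = sum(brain_roi)
  )
}

#' Intensity profile along a polyline
#'
#' Samples one or more channels along a scan polyline with bilinear
#' interpolation at sub-pixel steps, the standard read-out for wall
#' architecture (e.g. the two collagen-IV peaks at the borders of a vessel,
#' or the complementary SMA/MX04 profiles across a CAA-affected wall).
#'
#' @param image A [channel_image()].
#' @param polyline n x 2 matrix of (x, y) vertices in pixel coordinates.
#' @param channels Channel roles to sample (default: all).
#' @param normalize If `TRUE`, each channel is scaled to its own maximum.
#' @param step_px Sampling step along the polyline (<= 0.5 px).
#' @return Tibble with `position_um`, `channel`, `intensity`.
#' @export
line_profile <- function(image, polyline, channels = names(image$channels),
                         normalize = FALSE, step_px = 0.5) {
  stopifnot(inherits(image, "channel_image"))
  if (!is.matrix(polyline) || ncol(polyline) != 2 || nrow(polyline) < 2) {
    abort("`polyline` must be an n x 2 matrix with n >= 2.")
  }
  if (step_px <= 0 || step_px > 0.5) abort("`step_px` must be in (0, 0.5].")
  seg_len <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                           polyline[-nrow(polyline), , drop = FALSE])^2))
  total <- sum(seg_len)
  if (total == 0) abort("degenerate (zero-length) polyline.")
  s_vertices <- c(0, cumsum(seg_len))
  s <- seq(0, total, by = step_px)
  xs <- stats::approx(s_vertices, polyline[, 1], xout = s)$y
  ys <- stats::approx(s_vertices, polyline[, 2], xout = s)$y
  d <- dim(image$channels[[1]])
  if (any(xs < 0.5 | xs > d[2] - 0.5 | ys < 0.5 | ys > d[1] - 0.5)) {
    abort("polyline leaves the interpolable image area.")
  }
  out <- map(channels, function(role) {
    ch <- get_channel(image, role)
    v <- bilinear_sample(ch, xs, ys)
    if (normalize && max(v) > 0) v <- v / max(v)
    tibble(position_um = s * image$pixel_size_um, channel = role, intensity = v)
  })
  bind_rows(out)
}

# Bilinear interpolation at (x, y) pixel coordinates; pixel (r, c) has
# center (c - 0.5, r - 0.5).
bilinear_sample <- function(m, x, y) {
  cx <- x + 0.5; cy <- y + 0.5 # to 1-based center coords
  c0 <- pmin(pmax(floor(cx), 1L), ncol(m) - 1L)
  r0 <- pmin(pmax(floor(cy), 1L), nrow(m) - 1L)
  fx <- cx - c0; fy <- cy - r0
  m[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
    m[cbind(r0, c0 + 1L)] * fx * (1 - fy) +
    m[cbind(r0 + 1L, c0)] * (1 - fx) * fy +
    m[cbind(r0 + 1L, c0 + 1L)] * fx * fy
}
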
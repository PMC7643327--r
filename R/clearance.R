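#' Count tracer-positive periarterial drainage arteries
#'
#' After intraparenchymal tracer injection, arteries draining solutes along
#' their walls carry both smooth-muscle (SMA) and tracer signal. This
#' operation counts connected SMA components, above a minimum area, whose
#' pixel overlap with the thresholded tracer channel reaches the
#' colocalization fraction. The component list is returned for audit.
#'
#' @param image A [channel_image()] with `SMA` and a tracer channel.
#' @param tracer Tracer channel role (default `"FITC3K"`).
#' @param sma_policy,tracer_policy Threshold policies for the two channels.
#' @param min_area_px Minimum SMA component area, px.
#' @param colocal_fraction Minimum fraction of component pixels that must be
#'   tracer-positive (default 0.3).
#' @param hemisphere_mask Optional logical matrix restricting the analysis
#'   to the injected hemisphere.
#' @return One-row tibble with `count`, the resolved thresholds and the
#'   criterion record; the per-component audit table (area, overlap
#'   fraction, accepted) is attached as attribute `components`.
#' @export
count_ipad_arteries <- function(image, tracer = "FITC3K",
                                sma_policy = threshold_otsu(),
                                tracer_policy = threshold_otsu(),
                                min_area_px = 20,
                                colocal_fraction = 0.3,
                                hemisphere_mask = NULL) {
  sma <- get_channel(image, "SMA")
  trc <- get_channel(image, tracer)
  sma_thr <- resolve_threshold(sma_policy, sma)
  trc_thr <- resolve_threshold(tracer_policy, trc)
  sma_bin <- sma > sma_thr
  trc_bin <- trc > trc_thr
  if (!is.null(hemisphere_mask)) {
    sma_bin <- sma_bin & hemisphere_mask
    trc_bin <- trc_bin & hemisphere_mask
  }
  comp <- label_components(sma_bin)
  audit <- comp_audit(comp, trc_bin, min_area_px, colocal_fraction)
  out <- tibble(
    slice_id = image$slice_id,
    count = sum(audit$accepted),
    sma_threshold = sma_thr,
    tracer_threshold = trc_thr,
    min_area_px = min_area_px,
    colocal_fraction = colocal_fraction
  )
  attr(out, "components") <- audit
  out
}

label_components <- function(bin) {
  if (!any(bin)) return(matrix(0L, nrow(bin), ncol(bin)))
  m <- EBImage::bwlabel(bin * 1)
  matrix(as.integer(m), nrow(bin), ncol(bin))
}

comp_audit <- function(comp, trc_bin, min_area_px, colocal_fraction) {
  k <- max(comp)
  if (k == 0) {
    return(tibble(component = integer(), area_px = integer(),
                  overlap_fraction = double(), accepted = logical()))
  }
  area <- tabulate(comp[comp > 0], nbins = k)
  overlap <- tabulate(comp[comp > 0 & trc_bin], nbins = k)
  frac <- ifelse(area > 0, overlap / area, 0)
  tibble(
    component = seq_len(k),
    area_px = area,
    overlap_fraction = frac,
    accepted = area >= min_area_px & frac >= colocal_fraction
  )
}

#' Whole-slice CSF influx signal
#'
#' Treats the entire brain slice as one region of interest and reports the
#' background-subtracted mean and integrated tracer intensity over the brain
#' mask. The background is estimated as the median intensity outside the
#' brain mask by default (so adding a constant offset to the whole image
#' leaves the result unchanged), or from an explicit background mask.
#'
#' @param slice A [cortical_slice()] (or a [channel_image()] plus
#'   `brain_mask`).
#' @param channel Tracer channel role.
#' @param brain_mask Required when `slice` is a [channel_image()].
#' @param background_mask Optional explicit background region.
#' @return One-row tibble: `slice_id`, `channel`, `mean_signal`,
#'   `total_signal`, `background`, `n_px`.
#' @export
total_influx_signal <- function(slice, channel, brain_mask = NULL,
                                background_mask = NULL) {
  if (inherits(slice, "cortical_slice")) {
    image <- slice$image
    brain_mask <- brain_mask %||% slice$brain_mask
  } else {
    image <- slice
    if (is.null(brain_mask)) abort("`brain_mask` is required.")
  }
  ch <- get_channel(image, channel)
  if (!is.logical(brain_mask) || !identical(dim(brain_mask), dim(ch)) ||
      !any(brain_mask)) {
    abort("`brain_mask` must be a non-empty logical matrix matching the image.")
  }
  bg_px <- if (is.null(background_mask)) !brain_mask else background_mask
  if (!any(bg_px)) abort("background region is empty.")
  bg <- median(ch[bg_px])
  vals <- ch[brain_mask] - bg
  tibble(
    slice_id = image$slice_id,
    channel = channel,
    mean_signal = mean(vals),
    total_signal = sum(vals),
    background = bg,
    n_px = sum(brain_mask)
  )
}

#' Count penetrating vessels perpendicular to the cortex
#'
#' Merges the two tracer channels (pixel-wise maximum), thresholds the
#' merged image within the cortical band, and counts elongated connected
#' components whose principal axis lies within an angular tolerance of the
#' local cortical normal (the radial direction from the slice center at the
#' component centroid). Defaults: aspect ratio >= 2, +-30 degrees.
#'
#' @param slice A [cortical_slice()].
#' @param channels Tracer channel roles to merge.
#' @param policy Threshold policy on the merged band pixels.
#' @param min_aspect Minimum major/minor axis ratio.
#' @param angle_tol_deg Angular tolerance to the local normal, degrees.
#' @param min_area_px Minimum component area.
#' @return One-row tibble with `count` and the criterion record; the
#'   per-component audit table is attached as attribute `components`.
#' @export
count_penetrating_vessels <- function(slice, channels = c("FITC3K", "TMR40K"),
                                      policy = threshold_otsu(),
                                      min_aspect = 2, angle_tol_deg = 30,
                                      min_area_px = 10) {
  stopifnot(inherits(slice, "cortical_slice"))
  present <- intersect(channels, names(slice$image$channels))
  if (length(present) == 0) abort("none of the requested tracer channels present.")
  merged <- Reduce(pmax, lapply(present, function(r) get_channel(slice$image, r)))
  band <- slice$cortex_mask
  thr <- resolve_threshold(policy, merged[band])
  bin <- band & merged > thr
  comp <- label_components(bin)
  k <- max(comp)
  rows <- vector("list", k)
  if (k > 0) {
    for (i in seq_len(k)) {
      idx <- which(comp == i)
      if (length(idx) < min_area_px) {
        rows[[i]] <- tibble(component = i, area_px = length(idx),
                            aspect = NA_real_, normal_dev_deg = NA_real_,
                            accepted = FALSE)
        next
      }
      rr <- ((idx - 1) %% nrow(comp)) + 0.5
      cc <- ((idx - 1) %/% nrow(comp)) + 0.5
      shp <- blob_shape(cbind(cc, rr))
      normal <- atan2(mean(rr) - slice$center[2],
                      mean(cc) - slice$center[1]) * 180 / pi
      dev <- angle_diff(shp$orientation_deg, normal)
      rows[[i]] <- tibble(
        component = i, area_px = length(idx), aspect = shp$aspect,
        normal_dev_deg = dev,
        accepted = shp$aspect >= min_aspect & dev <= angle_tol_deg
      )
    }
  }
  audit <- if (k > 0) bind_rows(rows) else
    tibble(component = integer(), area_px = integer(), aspect = double(),
           normal_dev_deg = double(), accepted = logical())
  out <- tibble(
    slice_id = slice$image$slice_id,
    count = sum(audit$accepted),
    threshold = thr,
    min_aspect = min_aspect,
    angle_tol_deg = angle_tol_deg,
    min_area_px = min_area_px
  )
  attr(out, "components") <- audit
  attr(out, "labels") <- comp
  out
}

#' Partition the cortical band into dorsal, lateral and ventral regions
#'
#' Splits the cortical band at the two landmark angles measured from the
#' dorsal midline (standing in for the anatomical boundaries at the primary
#' somatosensory and piriform cortex). The three masks are disjoint and
#' cover the band exactly; degenerate empty regions (landmarks at the band
#' ends or coincident) are flagged with a warning, not an error.
#'
#' @param slice A [cortical_slice()].
#' @param landmarks_deg Optional override of the slice's landmark angles.
#' @return Named list of logical masks `dorsal`, `lateral`, `ventral`.
#' @export
partition_cortex <- function(slice, landmarks_deg = NULL) {
  stopifnot(inherits(slice, "cortical_slice"))
  lm <- landmarks_deg %||% slice$landmarks_deg
  if (length(lm) != 2 || any(!is.finite(lm))) {
    abort("two finite landmark angles are required.")
  }
  if (diff(lm) < 0) abort("landmarks must be ordered along the band.")
  ang <- band_angle(slice)
  band <- slice$cortex_mask
  masks <- list(
    dorsal = band & ang < lm[1],
    lateral = band & ang >= lm[1] & ang < lm[2],
    ventral = band & ang >= lm[2]
  )
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty)) {
    warn(paste0("degenerate partition: empty region(s): ",
                paste(empty, collapse = ", ")))
  }
  masks
}

#' Linearize the cortical band along arclength from the midline
#'
#' Unrolls the cortical band along its arclength starting at the dorsal
#' midline and reports the mean intensity of each channel in consecutive
#' arclength bins, with the region label carried along — the standard way to
#' display a dorsoventral influx gradient as a 1-D profile.
#'
#' @param slice A [cortical_slice()].
#' @param channels Channel roles to profile (default: all).
#' @param n_bins Number of arclength bins over the 0-180 degree sweep.
#' @param band_depth_um Optional restriction of the band to the given depth
#'   from its outer edge; must be positive.
#' @return Tibble with `arclength_um`, `angle_deg`, `region`, `channel`,
#'   `mean_intensity`, `n_px`.
#' @export
linearize_cortex <- function(slice, channels = names(slice$image$channels),
                             n_bins = 36, band_depth_um = NULL) {
  stopifnot(inherits(slice, "cortical_slice"))
  band <- slice$cortex_mask
  if (!is.null(band_depth_um)) {
    if (band_depth_um <= 0) abort("`band_depth_um` must be positive.")
    d <- dim(band)
    cx <- rep(seq_len(d[2]) - 0.5, each = d[1])
    cy <- rep(seq_len(d[1]) - 0.5, times = d[2])
    r <- matrix(sqrt((cx - slice$center[1])^2 + (cy - slice$center[2])^2),
                d[1], d[2])
    r_out <- max(r[band])
    band <- band & r >= r_out - band_depth_um / slice$image$pixel_size_um
  }
  ang <- band_angle(slice)
  idx <- which(band)
  bins <- pmin(n_bins, 1L + floor(ang[idx] / (180 / n_bins)))
  lm <- slice$landmarks_deg
  # mean radius gives the arclength scale of the band midline
  d <- dim(band)
  cx <- ((idx - 1) %/% d[1]) + 0.5
  cy <- ((idx - 1) %% d[1]) + 0.5
  r_mid <- mean(sqrt((cx - slice$center[1])^2 + (cy - slice$center[2])^2))
  centers_deg <- (seq_len(n_bins) - 0.5) * 180 / n_bins
  out <- map(channels, function(role) {
    ch <- get_channel(slice$image, role)
    v <- ch[idx]
    mean_v <- tapply(v, bins, mean)
    n_v <- tapply(v, bins, length)
    present <- as.integer(names(mean_v))
    tibble(
      angle_deg = centers_deg[present],
      arclength_um = centers_deg[present] * pi / 180 * r_mid *
        slice$image$pixel_size_um,
      region = ifelse(centers_deg[present] < lm[1], "dorsal",
                      ifelse(centers_deg[present] < lm[2], "lateral", "ventral")),
      channel = role,
      mean_intensity = as.numeric(mean_v),
      n_px = as.integer(n_v)
    )
  })
  bind_rows(out)
}

#' Regional signal table over a slice cohort
#'
#' Assembles, per slice and region, the background-subtracted mean and
#' integrated tracer signal, the plaque burden (via [plaque_coverage()]
#' restricted to the region mask), and the penetrating-vessel count whose
#' accepted components fall in the region. One row per slice x region x
#' channel; negative background-subtracted means are clipped to zero and
#' flagged in `clipped`.
#'
#' @param slices List of [cortical_slice()] objects.
#' @param channels Tracer channel roles (must be present in every slice).
#' @param plaque_policy Threshold policy for the plaque burden.
#' @param count_penetrating If `TRUE`, per-region penetrating-vessel counts
#'   are included.
#' @param ... Passed to [count_penetrating_vessels()].
#' @return A `RegionalSignalTable` tibble: `slice_id`, `region`, `channel`,
#'   `mean_signal`, `total_signal`, `plaque_burden_pct`,
#'   `n_penetrating_vessels`, `clipped`.
#' @export
regional_table <- function(slices, channels = c("FITC3K", "TMR40K"),
                           plaque_policy = threshold_fixed(0.3),
                           count_penetrating = TRUE, ...) {
  if (length(slices) == 0) abort("`slices` is empty.")
  for (s in slices) {
    if (!all(channels %in% names(s$image$channels))) {
      abort(paste0("slice `", s$slice_id, "` lacks requested channels: ",
                   paste(setdiff(channels, names(s$image$channels)),
                         collapse = ", ")))
    }
  }
  rows <- map(slices, function(s) {
    masks <- partition_cortex(s)
    bg_px <- !s$brain_mask
    counts <- if (count_penetrating) {
      pv <- count_penetrating_vessels(s, channels = channels, ...)
      assign_counts(s, attr(pv, "components"), attr(pv, "labels"))
    } else c(dorsal = NA_integer_, lateral = NA_integer_, ventral = NA_integer_)
    per_region <- map(names(masks), function(rg) {
      m <- masks[[rg]]
      if (!any(m)) {
        return(tibble(slice_id = s$slice_id, region = rg, channel = channels,
                      mean_signal = NA_real_, total_signal = NA_real_,
                      plaque_burden_pct = NA_real_,
                      n_penetrating_vessels = counts[[rg]], clipped = FALSE))
      }
      pb <- plaque_coverage(s$image, m, policy = plaque_policy,
                            background_mask = bg_px)$plaque_pct
      per_ch <- map(channels, function(chn) {
        ch <- get_channel(s$image, chn)
        bg <- median(ch[bg_px])
        mv <- mean(ch[m]) - bg
        tibble(
          slice_id = s$slice_id, region = rg, channel = chn,
          mean_signal = max(mv, 0), total_signal = max(sum(ch[m] - bg), 0),
          plaque_burden_pct = pb,
          n_penetrating_vessels = counts[[rg]],
          clipped = mv < 0
        )
      })
      bind_rows(per_ch)
    })
    bind_rows(per_region)
  })
  out <- bind_rows(rows)
  out$region <- factor(out$region, levels = c("dorsal", "lateral", "ventral"))
  arrange(out, .data$slice_id, .data$region, .data$channel)
}

# Assign accepted penetrating-vessel components to regions by mean angle.
assign_counts <- function(slice, comps, comp) {
  counts <- c(dorsal = 0L, lateral = 0L, ventral = 0L)
  acc <- comps[comps$accepted, , drop = FALSE]
  if (nrow(acc) == 0) return(counts)
  ang <- band_angle(slice)
  lm <- slice$landmarks_deg
  for (i in acc$component) {
    a <- mean(ang[comp == i])
    rg <- if (a < lm[1]) "dorsal" else if (a < lm[2]) "lateral" else "ventral"
    counts[[rg]] <- counts[[rg]] + 1L
  }
  counts
}
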
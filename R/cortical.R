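#' Coronal cortical slice records
#'
#' Container for one coronal slice in the clearance analysis: the
#' multi-channel image, the brain mask, and the geometry needed to partition
#' and linearize the cortical band — a center point, the dorsal midline
#' direction, the cortical band mask, and two landmark angles standing in
#' for the anatomical boundaries (primary somatosensory cortex and piriform
#' cortex) that separate the dorsal, lateral and ventral regions. Angles are
#' measured from the dorsal midline along the band, in degrees, so a point
#' at 0 deg is at the midline and 180 deg is fully ventral; both hemispheres
#' are treated symmetrically.
#'
#' @param image A [channel_image()].
#' @param brain_mask Logical matrix delimiting the brain.
#' @param cortex_mask Logical matrix delimiting the cortical band.
#' @param center Length-2 vector (x, y): the point the band wraps around.
#' @param midline_deg Direction of the dorsal midline from `center`, degrees
#'   (90 = straight up in pixel coordinates where y grows downward is 270;
#'   the synthetic generator uses 270, i.e. towards the top of the image).
#' @param landmarks_deg Length-2 increasing vector of boundary angles from
#'   the midline (default `c(60, 120)`).
#' @param slice_id,ap_position_mm Labels.
#' @return An object of class `cortical_slice`.
#' @export
cortical_slice <- function(image, brain_mask, cortex_mask, center,
                           midline_deg = 270, landmarks_deg = c(60, 120),
                           slice_id = "slice", ap_position_mm = NA_real_) {
  stopifnot(inherits(image, "channel_image"))
  d <- dim(image$channels[[1]])
  if (!is.logical(brain_mask) || !identical(dim(brain_mask), d) || !any(brain_mask)) {
    abort("`brain_mask` must be a non-empty logical matrix matching the image.")
  }
  if (!is.logical(cortex_mask) || !identical(dim(cortex_mask), d) || !any(cortex_mask)) {
    abort("`cortex_mask` must be a non-empty logical matrix matching the image.")
  }
  if (length(landmarks_deg) != 2 || diff(landmarks_deg) < 0 ||
      any(landmarks_deg < 0 | landmarks_deg > 180)) {
    abort("`landmarks_deg` must be two ordered angles in [0, 180].")
  }
  structure(
    list(image = image, brain_mask = brain_mask, cortex_mask = cortex_mask,
         center = center, midline_deg = midline_deg,
         landmarks_deg = landmarks_deg, slice_id = slice_id,
         ap_position_mm = ap_position_mm),
    class = "cortical_slice"
  )
}

# Angular distance (degrees, in [0, 180]) of each pixel center from the
# dorsal midline direction, viewed from the slice center.
band_angle <- function(slice) {
  d <- dim(slice$cortex_mask)
  cx <- rep(seq_len(d[2]) - 0.5, each = d[1])
  cy <- rep(seq_len(d[1]) - 0.5, times = d[2])
  ang <- atan2(cy - slice$center[2], cx - slice$center[1]) * 180 / pi
  diff <- abs((ang - slice$midline_deg + 180) %% 360 - 180)
  matrix(diff, d[1], d[2])
}

#' Specify a synthetic coronal-slice cohort with regional gradients
#'
#' Builds circular "coronal slices" whose cortical band carries
#' region-constant tracer signal (dorsal / lateral / ventral means per
#' tracer), parenchymal amyloid plaques at per-region burden targets, and
#' radially oriented penetrating-vessel stripes crossing the band. The
#' defaults encode the pattern the clearance analysis is designed to detect:
#' CSF-tracer influx highest ventrally and decreasing towards the dorsal
#' midline, with plaque burden running the opposite way.
#'
#' @param canvas_px Square canvas side, px.
#' @param radius_px Brain radius, px.
#' @param band_px Cortical band thickness, px.
#' @param landmarks_deg Region boundary angles from the dorsal midline.
#' @param influx_means Named list per tracer of `c(dorsal=, lateral=,
#'   ventral=)` mean added intensities (0-1 scale).
#' @param plaque_burden_pct `c(dorsal=, lateral=, ventral=)` target plaque
#'   burden, percent of region area.
#' @param n_penetrating Number of radial stripes across the band.
#' @param background_level,noise,pixel_size_um,seed As in [slice_spec()].
#' @return A `cortical_slice_spec` object.
#' @export
cortical_slice_spec <- function(canvas_px = 360L,
                                radius_px = 160,
                                band_px = 40,
                                landmarks_deg = c(60, 120),
                                influx_means = list(
                                  FITC3K = c(dorsal = 0.10, lateral = 0.20, ventral = 0.30),
                                  TMR40K = c(dorsal = 0.08, lateral = 0.16, ventral = 0.24)
                                ),
                                plaque_burden_pct = c(dorsal = 4, lateral = 2.5, ventral = 1),
                                n_penetrating = 12L,
                                background_level = 0.05,
                                noise = NULL,
                                pixel_size_um = 10,
                                seed = 1L) {
  stopifnot(radius_px < canvas_px / 2, band_px > 0, band_px < radius_px)
  for (m in influx_means) {
    if (!all(c("dorsal", "lateral", "ventral") %in% names(m)) || any(m < 0)) {
      abort("each influx_means entry needs non-negative dorsal/lateral/ventral values.")
    }
  }
  if (any(plaque_burden_pct < 0 | plaque_burden_pct > 100)) {
    abort("plaque_burden_pct values must lie in [0, 100].")
  }
  structure(
    list(canvas_px = as.integer(canvas_px), radius_px = radius_px,
         band_px = band_px, landmarks_deg = landmarks_deg,
         influx_means = influx_means, plaque_burden_pct = plaque_burden_pct,
         n_penetrating = as.integer(n_penetrating),
         background_level = background_level, noise = validate_noise(noise),
         pixel_size_um = pixel_size_um, seed = as.integer(seed)),
    class = "cortical_slice_spec"
  )
}

#' Render a synthetic cortical slice
#'
#' @param spec A [cortical_slice_spec()].
#' @param slice_id Label for the slice.
#' @return List with `slice` (a [cortical_slice()]) and `truth` (list with
#'   per-region achieved plaque burden, the influx means, and
#'   `n_penetrating`).
#' @export
make_cortical_slice <- function(spec, slice_id = "synthetic") {
  stopifnot(inherits(spec, "cortical_slice_spec"))
  n <- spec$canvas_px
  dm <- c(n, n)
  ctr <- c(n / 2, n / 2)
  brain <- disk_mask(dm, ctr[1], ctr[2], spec$radius_px)
  band <- annulus_mask(dm, ctr[1], ctr[2], spec$radius_px - spec$band_px,
                       spec$radius_px)
  # midline towards the image top: y grows downward, so direction 270 deg
  fake <- list(cortex_mask = band, center = ctr, midline_deg = 270)
  ang <- band_angle(fake)
  regions <- list(
    dorsal = band & ang < spec$landmarks_deg[1],
    lateral = band & ang >= spec$landmarks_deg[1] & ang < spec$landmarks_deg[2],
    ventral = band & ang >= spec$landmarks_deg[2]
  )

  zero <- matrix(0, n, n)
  channels <- list(SMA = zero, MX04 = zero)
  for (tr in names(spec$influx_means)) channels[[tr]] <- zero
  plaque_truth <- c(dorsal = NA_real_, lateral = NA_real_, ventral = NA_real_)

  with_seed(spec$seed, {
    for (tr in names(spec$influx_means)) {
      m <- channels[[tr]]
      for (rg in names(regions)) m[regions[[rg]]] <- spec$influx_means[[tr]][[rg]]
      channels[[tr]] <- m
    }
    # radial penetrating-vessel stripes spanning the band, avoiding region
    # boundaries so per-region counts are unambiguous
    if (spec$n_penetrating > 0) {
      bounds <- c(5, spec$landmarks_deg, 175)
      per <- diff(bounds)
      n_each <- round(spec$n_penetrating * per / sum(per))
      n_each[1] <- spec$n_penetrating - sum(n_each[-1])
      angs <- unlist(purrr::map2(seq_along(per), n_each, function(i, k) {
        if (k <= 0) return(numeric())
        seq(bounds[i] + 4, bounds[i + 1] - 4, length.out = k)
      }))
      n_per_region <- c(
        dorsal = sum(angs < spec$landmarks_deg[1]),
        lateral = sum(angs >= spec$landmarks_deg[1] & angs < spec$landmarks_deg[2]),
        ventral = sum(angs >= spec$landmarks_deg[2])
      )
      side <- sample(c(-1, 1), length(angs), replace = TRUE)
      for (i in seq_along(angs)) {
        th <- (270 + side[i] * angs[i]) * pi / 180
        r0 <- spec$radius_px - spec$band_px + 2
        r1 <- spec$radius_px - 2
        st <- segment_mask(dm,
                           ctr[1] + r0 * cos(th), ctr[2] + r0 * sin(th),
                           ctr[1] + r1 * cos(th), ctr[2] + r1 * sin(th),
                           width = 3)
        for (tr in names(spec$influx_means)) {
          m <- channels[[tr]]; m[st] <- pmax(m[st], 0.85); channels[[tr]] <- m
        }
      }
    }
    # plaques per region
    mx <- channels$MX04
    for (rg in names(regions)) {
      reg <- regions[[rg]]
      target <- spec$plaque_burden_pct[[rg]] / 100 * sum(reg)
      pl <- matrix(FALSE, n, n)
      guard <- 0L
      reg_idx <- which(reg)
      while (sum(pl & reg) < target && guard < 5000L) {
        seed_px <- sample(reg_idx, 1)
        y0 <- ((seed_px - 1) %% n) + 0.5
        x0 <- ((seed_px - 1) %/% n) + 0.5
        pl <- pl | disk_mask(dm, x0, y0, stats::runif(1, 2, 4.5))
        guard <- guard + 1L
      }
      mx[pl & reg] <- pmax(mx[pl & reg], 0.8)
      plaque_truth[[rg]] <- 100 * sum(pl & reg) / sum(reg)
    }
    channels$MX04 <- mx
    # uniform autofluorescence/detector floor over the whole canvas, so the
    # outside-brain region is a faithful background reference
    channels <- lapply(channels, function(m) m + spec$background_level)
    if (!is.null(spec$noise)) channels <- lapply(channels, apply_noise, spec$noise)
    channels <- lapply(channels, quantize16)
  })

  img <- channel_image(channels, spec$pixel_size_um, slice_id = slice_id)
  slice <- cortical_slice(img, brain_mask = brain, cortex_mask = band,
                          center = ctr, midline_deg = 270,
                          landmarks_deg = spec$landmarks_deg,
                          slice_id = slice_id)
  list(
    slice = slice,
    truth = list(
      plaque_burden_pct = plaque_truth,
      influx_means = spec$influx_means,
      n_penetrating = spec$n_penetrating,
      n_penetrating_per_region = if (spec$n_penetrating > 0) n_per_region else
        c(dorsal = 0L, lateral = 0L, ventral = 0L),
      regions = regions
    )
  )
}
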
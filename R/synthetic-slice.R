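#' Specify a synthetic immunofluorescence slice image
#'
#' Defines a flat multi-channel test image with known ground truth: ring
#' vessels whose walls carry smooth-muscle (SMA) signal over a specified
#' angular fraction and amyloid (MX04) over the complementary fraction
#' (mimicking amyloid replacing smooth muscle in CAA), a collagen-IV
#' network drawn to a specified area fraction, parenchymal MX04 plaques at a
#' specified burden, CSF-tracer filling of selected vessels (tracer-positive
#' periarterial drainage arteries), and elongated cortex-perpendicular
#' tracer stripes (penetrating vessels, drawn vertically: the synthetic
#' cortical surface is the top edge).
#'
#' @param canvas_px Length-2 integer vector `c(width, height)`.
#' @param pixel_size_um Micrometres per pixel.
#' @param vessels Data frame with one row per vessel: `x`, `y`, `radius_px`,
#'   `type` (surface/penetrating artery), `sma_fraction`, `mx04_fraction`
#'   (each in `[0, 1]`, summing to at most 1 per vessel),
#'   `tracer_positive` (logical). May have zero rows.
#' @param wall_px Ring wall thickness in pixels.
#' @param collagen_fraction Target collagen-IV area fraction of the canvas
#'   (`NULL` to omit the channel).
#' @param plaque_fraction Target parenchymal plaque area fraction (`NULL` to
#'   omit plaques; the MX04 channel is still present if vessels carry MX04).
#' @param n_penetrating Number of vertical tracer stripes (0 for none).
#' @param background_level Additive background on the 0-1 intensity scale.
#' @param noise Noise model as in [kymograph_spec()].
#' @param seed Integer seed.
#' @return A `slice_spec` object.
#' @export
slice_spec <- function(canvas_px = c(400L, 400L),
                       pixel_size_um = 1,
                       vessels = default_vessel_layout(),
                       wall_px = 4,
                       collagen_fraction = NULL,
                       plaque_fraction = NULL,
                       n_penetrating = 0L,
                       background_level = 0.05,
                       noise = NULL,
                       seed = 1L) {
  vessels <- as_tibble(vessels)
  needed <- c("x", "y", "radius_px", "type", "sma_fraction", "mx04_fraction",
              "tracer_positive")
  if (nrow(vessels) > 0 && !all(needed %in% names(vessels))) {
    abort(paste0("`vessels` must have columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(vessels) > 0) {
    fr <- c(vessels$sma_fraction, vessels$mx04_fraction)
    if (any(fr < 0 | fr > 1)) {
      abort("coverage fractions must lie in [0, 1].")
    }
    if (any(vessels$sma_fraction + vessels$mx04_fraction > 1 + 1e-9)) {
      abort("sma_fraction + mx04_fraction must not exceed 1 for any vessel.")
    }
    if (any(vessels$x - vessels$radius_px < 0 |
            vessels$x + vessels$radius_px > canvas_px[1] |
            vessels$y - vessels$radius_px < 0 |
            vessels$y + vessels$radius_px > canvas_px[2])) {
      abort("vessel layout overflows the canvas.")
    }
  }
  if (!is.null(collagen_fraction) &&
      (collagen_fraction < 0 || collagen_fraction > 1)) {
    abort("`collagen_fraction` must lie in [0, 1].")
  }
  if (!is.null(plaque_fraction) &&
      (plaque_fraction < 0 || plaque_fraction > 1)) {
    abort("`plaque_fraction` must lie in [0, 1].")
  }
  structure(
    list(canvas_px = as.integer(canvas_px), pixel_size_um = pixel_size_um,
         vessels = vessels, wall_px = wall_px,
         collagen_fraction = collagen_fraction,
         plaque_fraction = plaque_fraction,
         n_penetrating = as.integer(n_penetrating),
         background_level = background_level,
         noise = validate_noise(noise), seed = as.integer(seed)),
    class = "slice_spec"
  )
}

#' @rdname slice_spec
#' @export
default_vessel_layout <- function() {
  tibble(
    x = c(80, 200, 320, 120, 280),
    y = c(90, 80, 100, 260, 280),
    radius_px = c(20, 16, 22, 14, 18),
    type = c("surface_artery", "surface_artery", "penetrating_artery",
             "penetrating_artery", "surface_artery"),
    sma_fraction = c(0.9, 0.6, 0.75, 0.5, 0.3),
    mx04_fraction = c(0.1, 0.4, 0.25, 0.5, 0.7),
    tracer_positive = c(TRUE, FALSE, TRUE, TRUE, FALSE)
  )
}

#' Render a synthetic slice image with per-object ground truth
#'
#' Draws the layout of a [slice_spec()] and returns both the image and the
#' achieved (pixel-counted) ground truth, so downstream recovery tests
#' compare against what was actually rasterized rather than the nominal
#' request. Intensities are quantized to a 16-bit grid for lossless TIFF
#' round trips.
#'
#' @param spec A [slice_spec()].
#' @return List with `image` (a [channel_image()]), `vessels` (tibble of
#'   per-vessel achieved SMA/MX04 coverage fractions, tracer positivity and
#'   the wall mask pixel count) and `summary` (one-row tibble with achieved
#'   `collagen_fraction`, `plaque_fraction`, `n_tracer_positive`,
#'   `n_penetrating`). The drawn wall masks are attached as attribute
#'   `masks` on `vessels`.
#' @export
make_slice_image <- function(spec) {
  stopifnot(inherits(spec, "slice_spec"))
  w <- spec$canvas_px[1]; h <- spec$canvas_px[2]
  dm <- c(h, w) # matrix dim: rows = y, cols = x
  zero <- matrix(0, h, w)
  sma <- zero; mx <- zero; fitc <- zero; tmr <- zero
  masks <- list()
  truth <- list()

  with_seed(spec$seed, {
    vs <- spec$vessels
    if (nrow(vs) > 0) {
      for (i in seq_len(nrow(vs))) {
        ring <- annulus_mask(dm, vs$x[i], vs$y[i],
                             vs$radius_px[i] - spec$wall_px, vs$radius_px[i])
        idx <- which(ring)
        # order ring pixels by angle from a random start so SMA and MX04 arcs
        # are complementary, never overlapping
        rr <- ((idx - 1) %% h) + 1; cc <- ((idx - 1) %/% h) + 1
        ang <- atan2((rr - 0.5) - vs$y[i], (cc - 0.5) - vs$x[i])
        start <- stats::runif(1, -pi, pi)
        ord <- order((ang - start) %% (2 * pi))
        n_ring <- length(idx)
        n_sma <- round(vs$sma_fraction[i] * n_ring)
        n_mx <- min(round(vs$mx04_fraction[i] * n_ring), n_ring - n_sma)
        sma_idx <- idx[ord][seq_len(n_sma)]
        mx_idx <- idx[ord][n_sma + seq_len(n_mx)]
        sma[sma_idx] <- 0.85
        mx[mx_idx] <- 0.85
        if (isTRUE(vs$tracer_positive[i])) {
          lum <- disk_mask(dm, vs$x[i], vs$y[i], vs$radius_px[i])
          fitc[lum] <- pmax(fitc[lum], 0.8)
        }
        masks[[i]] <- ring
        truth[[i]] <- tibble(
          vessel = i, type = vs$type[i],
          sma_coverage = n_sma / n_ring,
          mx04_coverage = n_mx / n_ring,
          tracer_positive = isTRUE(vs$tracer_positive[i]),
          n_wall_px = n_ring
        )
      }
    }

    coliv <- NULL
    collagen_fraction <- NA_real_
    if (!is.null(spec$collagen_fraction)) {
      coliv <- zero
      target <- spec$collagen_fraction * length(coliv)
      net <- matrix(FALSE, h, w)
      guard <- 0L
      while (sum(net) < target && guard < 10000L) {
        x1 <- stats::runif(1, 0, w); y1 <- stats::runif(1, 0, h)
        th <- stats::runif(1, 0, pi); len <- stats::runif(1, 20, 80)
        net <- net | segment_mask(dm, x1, y1, x1 + len * cos(th),
                                  y1 + len * sin(th), width = 2.5)
        guard <- guard + 1L
      }
      coliv[net] <- 0.8
      collagen_fraction <- sum(net) / length(net)
    }

    plaque_fraction <- NA_real_
    if (!is.null(spec$plaque_fraction)) {
      target <- spec$plaque_fraction * h * w
      pl <- matrix(FALSE, h, w)
      guard <- 0L
      while (sum(pl) < target && guard < 5000L) {
        r <- stats::runif(1, 3, 7)
        x0 <- stats::runif(1, r, w - r); y0 <- stats::runif(1, r, h - r)
        pl <- pl | disk_mask(dm, x0, y0, r)
        guard <- guard + 1L
      }
      mx[pl] <- pmax(mx[pl], 0.8)
      plaque_fraction <- sum(pl) / length(pl)
    }

    if (spec$n_penetrating > 0) {
      xs <- seq(15, w - 15, length.out = spec$n_penetrating)
      for (x0 in xs) {
        st <- segment_mask(dm, x0, 8, x0, 48, width = 3)
        fitc[st] <- pmax(fitc[st], 0.8)
        tmr[st] <- pmax(tmr[st], 0.8)
      }
    }

    channels <- list(SMA = sma, MX04 = mx, FITC3K = fitc, TMR40K = tmr)
    if (!is.null(coliv)) channels$COLIV <- coliv
    channels <- lapply(channels, function(m) m + spec$background_level)
    if (!is.null(spec$noise)) channels <- lapply(channels, apply_noise, spec$noise)
    channels <- lapply(channels, quantize16)
  })

  img <- channel_image(channels, spec$pixel_size_um, slice_id = "synthetic")
  vessels <- if (length(truth)) bind_rows(truth) else tibble(
    vessel = integer(), type = character(), sma_coverage = double(),
    mx04_coverage = double(), tracer_positive = logical(), n_wall_px = integer()
  )
  attr(vessels, "masks") <- masks
  list(
    image = img,
    vessels = vessels,
    summary = tibble(
      collagen_fraction = collagen_fraction,
      plaque_fraction = plaque_fraction,
      n_tracer_positive = if (nrow(vessels)) sum(vessels$tracer_positive) else 0L,
      n_penetrating = spec$n_penetrating
    )
  )
}
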
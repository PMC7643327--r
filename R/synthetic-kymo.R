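#' Specify a synthetic pulsating-vessel kymograph
#'
#' Defines the ground-truth diameter dynamics and imaging model for a
#' simulated line scan: a bright lumen (the intravascular-dye convention)
#' whose diameter follows
#' `D(t) = baseline + amplitude * sin(2 pi f t) + drift * t`,
#' rendered with area-weighted (sub-pixel) wall edges, optional gaussian
#' blurring of the walls and optional noise. The cardiac band in mouse is
#' roughly 5-10 Hz; the default line period of 1 ms corresponds to a typical
#' ~1 kHz two-photon line rate.
#'
#' @param baseline_diameter_um Resting vessel diameter, um.
#' @param pulse_amplitude_um Peak sinusoidal diameter excursion, um.
#' @param pulse_frequency_hz Pulse frequency, Hz.
#' @param duration_ms Record length, ms; at least 3000 so one full epoch of
#'   the pulsatility integral is available.
#' @param line_period_ms Time per scanned line, ms.
#' @param pixel_size_um Spatial sampling along the scan line, um per pixel.
#' @param wall_blur_sigma_px Gaussian blur of the wall edges, pixels.
#' @param noise Noise model: `NULL` (none), `list(type = "gaussian", sigma =
#'   s)` with `s` on the 0-1 intensity scale, or `list(type = "poisson",
#'   scale = k)` (expected photon count `k` at intensity 1).
#' @param drift_um_per_s Slow linear drift of the baseline diameter, um/s.
#' @param seed Integer seed; identical specs and seeds reproduce the
#'   kymograph bit-identically.
#' @return A `kymograph_spec` object.
#' @export
kymograph_spec <- function(baseline_diameter_um = 10,
                           pulse_amplitude_um = 0.5,
                           pulse_frequency_hz = 7,
                           duration_ms = 6000,
                           line_period_ms = 1,
                           pixel_size_um = 0.25,
                           wall_blur_sigma_px = 1,
                           noise = NULL,
                           drift_um_per_s = 0,
                           seed = 1L) {
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort(paste0("invalid kymograph spec: `", nm, "` must be a positive number."))
    }
  }
  check_pos(baseline_diameter_um, "baseline_diameter_um")
  check_pos(pulse_frequency_hz, "pulse_frequency_hz")
  check_pos(duration_ms, "duration_ms")
  check_pos(line_period_ms, "line_period_ms")
  check_pos(pixel_size_um, "pixel_size_um")
  if (pulse_amplitude_um < 0) {
    abort("invalid kymograph spec: `pulse_amplitude_um` must be non-negative.")
  }
  if (wall_blur_sigma_px < 0) {
    abort("invalid kymograph spec: `wall_blur_sigma_px` must be non-negative.")
  }
  if (baseline_diameter_um - pulse_amplitude_um <= 0) {
    abort(paste0("invalid kymograph spec: baseline_diameter_um - ",
                 "pulse_amplitude_um must be positive (lumen must not close)."))
  }
  # Nyquist: at least 2 samples per pulse period.
  if (line_period_ms > 1000 / (2 * pulse_frequency_hz)) {
    abort(paste0("invalid kymograph spec: line_period_ms too long for ",
                 "pulse_frequency_hz (need >= 2 samples per pulse period)."))
  }
  noise <- validate_noise(noise)
  structure(
    list(
      baseline_diameter_um = baseline_diameter_um,
      pulse_amplitude_um = pulse_amplitude_um,
      pulse_frequency_hz = pulse_frequency_hz,
      duration_ms = duration_ms,
      line_period_ms = line_period_ms,
      pixel_size_um = pixel_size_um,
      wall_blur_sigma_px = wall_blur_sigma_px,
      noise = noise,
      drift_um_per_s = drift_um_per_s,
      seed = as.integer(seed)
    ),
    class = "kymograph_spec"
  )
}

validate_noise <- function(noise) {
  if (is.null(noise)) return(NULL)
  if (!is.list(noise) || is.null(noise$type)) {
    abort("`noise` must be NULL or list(type = , ...).")
  }
  type <- match.arg(noise$type, c("gaussian", "poisson"))
  if (type == "gaussian") {
    s <- noise$sigma
    if (!is.numeric(s) || s < 0) abort("gaussian noise needs `sigma` >= 0.")
    list(type = "gaussian", sigma = s)
  } else {
    k <- noise$scale
    if (!is.numeric(k) || k <= 0) abort("poisson noise needs `scale` > 0.")
    list(type = "poisson", scale = k)
  }
}

#' Generate a synthetic kymograph with known diameter dynamics
#'
#' Renders, line by line, a bright lumen of width `D(t)` centered on the scan
#' line. Wall edges are area-weighted, so sub-pixel diameter tracking is
#' testable; the exact analytic `D(t)` at each sample is returned as ground
#' truth. Intensities are quantized to a 16-bit grid so the image serializes
#' to TIFF losslessly.
#'
#' @param spec A [kymograph_spec()].
#' @param vessel_id,vessel_type,annotations Labels forwarded to the
#'   [kymograph()] constructor.
#' @return A list with elements `kymograph` (a [kymograph()], intensities in
#'   `[0, 1]`) and `truth` (tibble with `t_ms`, `D_um`).
#' @examples
#' sim <- make_kymograph(kymograph_spec(pulse_amplitude_um = 1, seed = 7))
#' sim$truth
#' @export
make_kymograph <- function(spec, vessel_id = "synthetic",
                           vessel_type = "surface_artery",
                           annotations = list()) {
  stopifnot(inherits(spec, "kymograph_spec"))
  n_t <- floor(spec$duration_ms / spec$line_period_ms)
  t_ms <- (seq_len(n_t) - 1L) * spec$line_period_ms
  D_um <- spec$baseline_diameter_um +
    spec$pulse_amplitude_um * sin(2 * pi * spec$pulse_frequency_hz * t_ms / 1000) +
    spec$drift_um_per_s * t_ms / 1000
  if (any(D_um <= 0)) abort("spec drift closes the lumen during the record.")

  px <- spec$pixel_size_um
  max_half <- max(D_um) / 2
  margin_um <- max(2, 4 * spec$wall_blur_sigma_px * px + 2)
  n_px <- 2L * ceiling((max_half + margin_um) / px) + 1L
  center_um <- n_px * px / 2

  # Area-weighted lumen coverage per pixel: pixel i spans [(i-1) px, i px].
  lo_edge <- (seq_len(n_px) - 1) * px
  hi_edge <- seq_len(n_px) * px
  img <- matrix(0, nrow = n_px, ncol = n_t)
  for (j in seq_len(n_t)) {
    a <- center_um - D_um[j] / 2
    b <- center_um + D_um[j] / 2
    overlap <- pmax(0, pmin(hi_edge, b) - pmax(lo_edge, a))
    col <- overlap / px
    if (spec$wall_blur_sigma_px > 0) col <- gauss_smooth(col, spec$wall_blur_sigma_px)
    img[, j] <- col
  }
  # Contrast 0.1 -> 0.9 so gaussian noise rarely clips at the quantization.
  img <- 0.1 + 0.8 * img
  if (!is.null(spec$noise)) {
    img <- with_seed(spec$seed, apply_noise(img, spec$noise))
  }
  img <- quantize16(img)

  kymo <- kymograph(img,
    pixel_size_um = px, line_period_ms = spec$line_period_ms,
    vessel_id = vessel_id, vessel_type = vessel_type,
    annotations = annotations
  )
  list(kymograph = kymo, truth = tibble(t_ms = t_ms, D_um = D_um))
}

apply_noise <- function(img, noise) {
  if (noise$type == "gaussian") {
    img + matrix(rnorm(length(img), sd = noise$sigma), nrow = nrow(img))
  } else {
    matrix(rpois(length(img), lambda = noise$scale * pmax(img, 0)) / noise$scale,
           nrow = nrow(img))
  }
}
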
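#' Extract a vessel diameter trace from a kymograph
#'
#' For each time line, the spatial intensity profile is lightly smoothed and
#' the vessel diameter is taken as the distance between the two wall
#' crossings of that profile at the detection level, with linear sub-pixel
#' interpolation between pixel centers. With the half-maximum method the
#' level is midway between the profile's minimum and maximum (the full-width
#' at half-maximum of a bright lumen); symmetric blurring of a wall edge
#' does not move its half-maximum crossing, so the estimate is robust to
#' moderate defocus. A zero-phase low-pass filter applied to the diameter
#' trace removes high-frequency information well above the cardiac band.
#'
#' Lines where no crossing pair is found are flagged invalid rather than
#' imputed; if more than 20% of lines are invalid the trace is rejected.
#'
#' @param kymo A [kymograph()] whose lumen is brighter than background.
#' @param method `"half_max"` (default) or `"threshold"` (fixed `level` on
#'   the intensity scale).
#' @param level Detection level for `method = "threshold"`.
#' @param smooth_cutoff_hz Cutoff of the zero-phase temporal low-pass applied
#'   to `D(t)`; `NULL` disables smoothing. Default 25 Hz, well above the
#'   mouse cardiac band (5-10 Hz).
#' @param profile_sigma_px Gaussian smoothing of each spatial profile before
#'   crossing detection, pixels.
#' @return A `diameter_trace`: a tibble with columns `t_ms`, `D_um`, `valid`
#'   and attributes recording the calibrations and smoothing provenance.
#' @export
extract_diameter_trace <- function(kymo, method = c("half_max", "threshold"),
                                   level = NULL, smooth_cutoff_hz = 25,
                                   profile_sigma_px = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  method <- match.arg(method)
  if (method == "threshold" && (is.null(level) || !is.numeric(level))) {
    abort("`level` must be given for the threshold method.")
  }
  img <- kymo$intensities
  n_t <- ncol(img)
  px <- kymo$pixel_size_um
  centers <- (seq_len(nrow(img)) - 0.5) # pixel centers, px units

  D_px <- rep(NA_real_, n_t)
  for (j in seq_len(n_t)) {
    p <- gauss_smooth(img[, j], profile_sigma_px)
    lev <- if (method == "half_max") (max(p) + min(p)) / 2 else level
    above <- p > lev
    if (!any(above) || all(above)) next
    runs <- rle(above)
    idx <- which(above)
    i1 <- idx[1]; i2 <- idx[length(idx)]
    if (i1 == 1L || i2 == length(p)) next # lumen touches the border
    # linear interpolation between pixel centers straddling the level
    left <- centers[i1 - 1] + (lev - p[i1 - 1]) / (p[i1] - p[i1 - 1])
    right <- centers[i2] + (lev - p[i2]) / (p[i2 + 1] - p[i2])
    if (!is.finite(left) || !is.finite(right) || right <= left) next
    D_px[j] <- right - left
  }
  valid <- is.finite(D_px)
  if (mean(!valid) > 0.20) {
    abort(paste0("no detectable lumen on ", sum(!valid), "/", n_t,
                 " lines (> 20%): trace rejected."))
  }
  D_um <- D_px * px
  if (!is.null(smooth_cutoff_hz)) {
    D_um <- lowpass_trace(D_um, valid, kymo$line_period_ms, smooth_cutoff_hz)
  }
  trace <- tibble(
    t_ms = (seq_len(n_t) - 1L) * kymo$line_period_ms,
    D_um = D_um,
    valid = valid
  )
  attr(trace, "line_period_ms") <- kymo$line_period_ms
  attr(trace, "vessel_id") <- kymo$vessel_id
  attr(trace, "vessel_type") <- kymo$vessel_type
  attr(trace, "annotations") <- kymo$annotations
  attr(trace, "smoothing") <- list(
    method = method, level = level,
    smooth_cutoff_hz = smooth_cutoff_hz, profile_sigma_px = profile_sigma_px
  )
  class(trace) <- c("diameter_trace", class(trace))
  trace
}

# Zero-phase Butterworth low-pass on D(t). Invalid samples are linearly
# interpolated for filtering only and stay flagged invalid. Odd (point-
# symmetric) extension at both ends keeps value and slope continuous there,
# suppressing filter edge transients.
lowpass_trace <- function(D_um, valid, line_period_ms, cutoff_hz) {
  fs <- 1000 / line_period_ms
  if (cutoff_hz >= fs / 2) return(D_um) # at/above Nyquist: nothing to remove
  x <- D_um
  if (any(!valid)) {
    if (sum(valid) < 2) return(D_um)
    x[!valid] <- stats::approx(which(valid), D_um[valid], xout = which(!valid),
                               rule = 2)$y
  }
  n <- length(x)
  half <- min(n - 1L, ceiling(fs / cutoff_hz) * 6L)
  pad <- c(2 * x[1] - x[(half + 1):2], x, 2 * x[n] - x[(n - 1):(n - half)])
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  signal::filtfilt(bf, pad)[(half + 1):(half + n)]
}

#' Construct a diameter trace directly from samples
#'
#' Mainly for testing and for traces produced outside the kymograph path.
#'
#' @param t_ms,D_um Sample times (ms) and diameters (um).
#' @param line_period_ms Sampling period; inferred from `t_ms` if omitted.
#' @param valid Logical vector flagging usable samples.
#' @return A `diameter_trace` tibble.
#' @export
diameter_trace <- function(t_ms, D_um, line_period_ms = NULL, valid = NULL) {
  stopifnot(length(t_ms) == length(D_um))
  if (is.null(line_period_ms)) line_period_ms <- median(diff(t_ms))
  if (is.null(valid)) valid <- is.finite(D_um)
  trace <- tibble(t_ms = t_ms, D_um = D_um, valid = valid)
  attr(trace, "line_period_ms") <- line_period_ms
  attr(trace, "smoothing") <- list(method = "direct")
  class(trace) <- c("diameter_trace", class(trace))
  trace
}

#' Moving-average diameter baseline
#'
#' Adds the moving-average baseline `d(t)` of the diameter trace `D(t)`,
#' computed with a centered window. Near the record ends, where the full
#' window no longer fits, the default policy holds the baseline at the
#' nearest full-window value: shrinking the window there leaks pulse phase
#' into the baseline and biases the pulsatility integral, whereas holding
#' keeps the baseline free of cardiac-band content everywhere. The
#' alternative `"shrink"` policy (progressively smaller clipped windows) is
#' retained for comparison. The policy and window are recorded in the trace
#' provenance because the pulsatility index depends on them.
#'
#' @param trace A `diameter_trace`.
#' @param window_ms Window length, ms. Default 500 ms spans several mouse
#'   cardiac periods, removing slow drift while preserving the pulse.
#' @param edge `"hold"` (default) or `"shrink"`.
#' @return The trace with a `d_um` column and provenance attributes
#'   `window_ms`, `edge_policy`, `mean_D_um` (static mean diameter).
#' @export
moving_average_baseline <- function(trace, window_ms = 500,
                                    edge = c("hold", "shrink")) {
  stopifnot(inherits(trace, "diameter_trace"))
  edge <- match.arg(edge)
  dt <- attr(trace, "line_period_ms")
  if (window_ms < 2 * dt) abort("`window_ms` must span at least two samples.")
  n <- nrow(trace)
  if (window_ms > (n - 1) * dt) abort("`window_ms` is longer than the record.")
  half <- round(window_ms / (2 * dt))
  D <- trace$D_um
  x <- D
  if (any(!trace$valid)) {
    x[!trace$valid] <- stats::approx(which(trace$valid), D[trace$valid],
                                     xout = which(!trace$valid), rule = 2)$y
  }
  csum <- cumsum(c(0, x))
  full <- seq_len(n) > half & seq_len(n) <= n - half
  d <- rep(NA_real_, n)
  i_full <- which(full)
  if (length(i_full) == 0) { # window == record: single centered value
    d[] <- mean(x)
  } else {
    d[i_full] <- (csum[i_full + half + 1] - csum[i_full - half]) / (2 * half + 1)
    if (edge == "hold") {
      d[seq_len(min(i_full) - 1)] <- d[min(i_full)]
      if (max(i_full) < n) d[(max(i_full) + 1):n] <- d[max(i_full)]
    } else {
      for (i in which(!full)) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        d[i] <- mean(x[lo:hi])
      }
    }
  }
  trace$d_um <- d
  attr(trace, "window_ms") <- window_ms
  attr(trace, "edge_policy") <- edge
  attr(trace, "mean_D_um") <- mean(D[trace$valid])
  trace
}

#' Vascular-wall pulsatility indices
#'
#' The absolute pulsatility index integrates the deviation of the diameter
#' curve from its moving-average baseline over 3000-ms epochs,
#' `sum |D(t) - d(t)| dt` (derived unit um.ms); it captures the absolute
#' extent of wall movement without encoding vessel size. The relative index
#' divides the deviation by the static mean diameter of the record before
#' integrating (unit ms), expressing movement relative to vessel caliber.
#' Both are computed per complete epoch as a rectangle (Riemann) sum with
#' `dt` equal to the line period and averaged over complete epochs; an
#' incomplete trailing epoch is discarded. Within an epoch, invalid samples
#' are excluded with the time base renormalized if they make up under 5% of
#' the epoch; epochs with more invalid samples are rejected.
#'
#' @param trace A `diameter_trace` with baseline (`d_um`) computed by
#'   [moving_average_baseline()].
#' @param epoch_ms Epoch length, ms (default 3000).
#' @return `pulsatility()` returns a one-row tibble with
#'   `pulsatility_index` (um.ms), `relative_pulsatility_index` (ms),
#'   `mean_diameter_um`, `n_epochs`, and the provenance columns `window_ms`
#'   and `edge_policy`; the per-epoch values are attached as attribute
#'   `per_epoch`. `pulsatility_index()` and `relative_pulsatility_index()`
#'   return the corresponding scalar.
#' @export
pulsatility <- function(trace, epoch_ms = 3000) {
  stopifnot(inherits(trace, "diameter_trace"))
  if (is.null(trace$d_um)) {
    abort("baseline missing: run moving_average_baseline() first.")
  }
  dt <- attr(trace, "line_period_ms")
  n_per <- floor(epoch_ms / dt)
  n <- nrow(trace)
  n_epochs <- floor(n / n_per)
  if (n_epochs < 1) abort("trace shorter than one complete epoch.")
  mean_D <- attr(trace, "mean_D_um") %||% mean(trace$D_um[trace$valid])
  if (!is.finite(mean_D) || mean_D <= 0) {
    abort("static mean diameter must be positive.")
  }
  dev <- abs(trace$D_um - trace$d_um)
  per_epoch <- rep(NA_real_, n_epochs)
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1) * n_per + 1):(e * n_per)
    ok <- trace$valid[idx]
    if (mean(!ok) >= 0.05) next # epoch rejected
    s <- sum(dev[idx][ok]) * dt
    per_epoch[e] <- s * n_per / sum(ok) # renormalize excluded samples
  }
  used <- is.finite(per_epoch)
  if (!any(used)) abort("no epoch passed the validity criterion.")
  tibble(
    pulsatility_index = mean(per_epoch[used]),
    relative_pulsatility_index = mean(per_epoch[used]) / mean_D,
    mean_diameter_um = mean_D,
    n_epochs = sum(used),
    window_ms = attr(trace, "window_ms") %||% NA_real_,
    edge_policy = attr(trace, "edge_policy") %||% NA_character_
  ) -> out
  attr(out, "per_epoch") <- per_epoch
  out
}

#' @rdname pulsatility
#' @export
pulsatility_index <- function(trace, epoch_ms = 3000) {
  pulsatility(trace, epoch_ms)$pulsatility_index
}

#' @rdname pulsatility
#' @export
relative_pulsatility_index <- function(trace, epoch_ms = 3000) {
  pulsatility(trace, epoch_ms)$relative_pulsatility_index
}

#' Batch pulsatility over a set of kymographs
#'
#' Runs diameter extraction, baseline computation and the pulsatility
#' indices on each kymograph and assembles a tidy per-vessel table suitable
#' for grouped summaries along the cerebrovascular tree (surface artery,
#' penetrating artery, surface vein, ascending vein).
#'
#' @param kymos List of [kymograph()] objects.
#' @param window_ms,epoch_ms,smooth_cutoff_hz Passed to the per-vessel steps.
#' @return A tibble with one row per vessel: `vessel_id`, `vessel_type`,
#'   `depth_um`, any annotation labels (e.g. `caa`), `mean_diameter_um`,
#'   both indices, `n_epochs` and a `qc_invalid_frac` column. Vessels whose
#'   trace is rejected appear with NA indices and the diagnostic in
#'   `qc_note`.
#' @export
batch_pulsatility <- function(kymos, window_ms = 500, epoch_ms = 3000,
                              smooth_cutoff_hz = 25) {
  if (length(kymos) == 0) {
    return(tibble(
      vessel_id = character(), vessel_type = character(),
      depth_um = double(), mean_diameter_um = double(),
      pulsatility_index = double(), relative_pulsatility_index = double(),
      n_epochs = integer(), qc_invalid_frac = double(), qc_note = character()
    ))
  }
  if (!all(vapply(kymos, inherits, logical(1), "kymograph"))) {
    abort("`kymos` must be a list of kymograph objects.")
  }
  rows <- map(kymos, function(k) {
    ann <- as_tibble(k$annotations %||% list())
    base <- tibble(
      vessel_id = k$vessel_id, vessel_type = k$vessel_type,
      depth_um = k$depth_um %||% NA_real_
    )
    res <- tryCatch({
      tr <- extract_diameter_trace(k, smooth_cutoff_hz = smooth_cutoff_hz)
      tr <- moving_average_baseline(tr, window_ms = window_ms)
      p <- pulsatility(tr, epoch_ms = epoch_ms)
      tibble(
        mean_diameter_um = p$mean_diameter_um,
        pulsatility_index = p$pulsatility_index,
        relative_pulsatility_index = p$relative_pulsatility_index,
        n_epochs = as.integer(p$n_epochs),
        qc_invalid_frac = mean(!tr$valid), qc_note = NA_character_
      )
    }, error = function(e) {
      tibble(
        mean_diameter_um = NA_real_, pulsatility_index = NA_real_,
        relative_pulsatility_index = NA_real_, n_epochs = 0L,
        qc_invalid_frac = NA_real_, qc_note = conditionMessage(e)
      )
    })
    dplyr::bind_cols(base, ann, res)
  })
  bind_rows(rows)
}
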
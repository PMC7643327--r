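#' Pipeline run configuration
#'
#' Validates a configuration for [run_pipeline()]. A config is a named list
#' (or a YAML file containing one) with a `seed`, the stages to run, and
#' per-stage parameters; every stage draws its synthetic inputs from the
#' corresponding spec so a complete run needs no external files.
#'
#' @param config Named list or path to a YAML file. Recognized fields:
#'   `seed` (integer), `stages` (subset of `"pulsatility"`, `"coverage"`,
#'   `"regional"`, `"regress"`), `n_vessels`, `pulse_amplitudes_um`,
#'   `window_ms`, `epoch_ms` (> 0, default 3000), `n_slices`, `tracer`.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or a YAML path.")
  defaults <- list(
    seed = 1L,
    stages = c("pulsatility", "coverage", "regional", "regress"),
    n_vessels = 8L,
    pulse_amplitudes_um = c(0.2, 0.4, 0.6, 0.8),
    window_ms = 500,
    epoch_ms = 3000,
    n_slices = 7L,
    tracer = "influx_3k"
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
  if (!is.numeric(cfg$epoch_ms) || cfg$epoch_ms <= 0) {
    abort("`epoch_ms` must be positive.")
  }
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if ("regress" %in% cfg$stages && !"regional" %in% cfg$stages) {
    abort("stage `regress` requires stage `regional`.")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the requested stages — simulate and analyze a kymograph cohort
#' (pulsatility), a slice image (coverage, density, plaque burden), a
#' coronal cohort (regional influx, counts) and the burden-influx
#' regression — writing one CSV per stage plus a JSON manifest recording the
#' config, package version, seed and an MD5 hash of every output, so a
#' deterministic run can be reproduced byte-identically.
#'
#' @param config See [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @examples
#' \donttest{
#' run_demo(file.path(tempdir(), "pvq-demo"), seed = 1)
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()

  write_out <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if ("pulsatility" %in% cfg$stages) {
    amps <- rep_len(cfg$pulse_amplitudes_um, cfg$n_vessels)
    types <- rep_len(vessel_types(), cfg$n_vessels)
    kymos <- map(seq_len(cfg$n_vessels), function(i) {
      spec <- kymograph_spec(
        baseline_diameter_um = 10 + 2 * (i %% 3),
        pulse_amplitude_um = amps[i],
        pulse_frequency_hz = 7,
        duration_ms = 6000,
        noise = list(type = "gaussian", sigma = 0.03),
        seed = cfg$seed * 1000L + i
      )
      make_kymograph(spec, vessel_id = sprintf("v%02d", i),
                     vessel_type = types[i],
                     annotations = list(caa = amps[i] >= stats::median(amps))
      )$kymograph
    })
    tbl <- batch_pulsatility(kymos, window_ms = cfg$window_ms,
                             epoch_ms = cfg$epoch_ms)
    write_out(tbl, "pulsatility.csv")
    write_out(
      group_summary(tbl, .data$vessel_type, value = "pulsatility_index"),
      "pulsatility_by_type.csv"
    )
  }

  if ("coverage" %in% cfg$stages) {
    sim <- make_slice_image(slice_spec(
      collagen_fraction = 0.12, plaque_fraction = 0.03,
      n_penetrating = 0L, seed = cfg$seed + 17L
    ))
    masks <- attr(sim$vessels, "masks")
    cov <- map(seq_len(nrow(sim$vessels)), function(i) {
      vm <- vessel_mask(sim$image,
                        vessel_roi(mask = masks[[i]], id = paste0("v", i)),
                        policy = threshold_fixed(0.3))
      bind_rows(
        channel_coverage(sim$image, vm, "SMA", threshold_fixed(0.3)),
        channel_coverage(sim$image, vm, "MX04", threshold_fixed(0.3))
      ) |> mutate(vessel = i, type = sim$vessels$type[i], .before = 1)
    }) |> bind_rows()
    write_out(cov, "coverage.csv")
    dens <- vascular_density(sim$image, center_px = c(200, 200),
                             policy = threshold_fixed(0.3))
    plq <- plaque_coverage(sim$image,
                           matrix(TRUE, nrow(sim$image$channels$MX04),
                                  ncol(sim$image$channels$MX04)),
                           policy = threshold_fixed(0.3))
    write_out(bind_rows(
      tibble(metric = "vascular_density_pct", value = dens$density_pct),
      tibble(metric = "plaque_coverage_pct", value = plq$plaque_pct)
    ), "slice_metrics.csv")
  }

  regional <- NULL
  if ("regional" %in% cfg$stages) {
    cohort <- map(seq_len(cfg$n_slices), function(i) {
      make_cortical_slice(
        cortical_slice_spec(noise = list(type = "gaussian", sigma = 0.01),
                            seed = cfg$seed * 100L + i),
        slice_id = sprintf("slice%02d", i)
      )
    })
    slices <- map(cohort, "slice")
    regional <- regional_table(slices)
    write_out(regional, "regional.csv")
    ipad_img <- make_slice_image(slice_spec(n_penetrating = 0L,
                                            seed = cfg$seed + 29L))$image
    write_out(count_ipad_arteries(ipad_img, sma_policy = threshold_fixed(0.3),
                                  tracer_policy = threshold_fixed(0.3)),
              "ipad_counts.csv")
  }

  if ("regress" %in% cfg$stages) {
    fit3 <- burden_influx_regression(
      filter(regional, .data$channel == "FITC3K"),
      influx = "mean_signal", burden = "plaque_burden_pct"
    )
    tabular <- make_regional_dataset(regional_gradient_spec(seed = cfg$seed))
    fit_tab <- burden_influx_regression(tabular, influx = cfg$tracer)
    reg <- bind_rows(
      mutate(glance(fit3), source = "image_cohort_FITC3K", .before = 1),
      mutate(glance(fit_tab), source = paste0("tabular_", cfg$tracer), .before = 1)
    )
    write_out(reg, "regression.csv")
  }

  manifest <- list(
    package = "pvq",
    version = as.character(utils::packageVersion("pvq")),
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname run_pipeline
#' @param seed Integer seed for the demo cohort.
#' @export
run_demo <- function(out_dir, seed = 1L) {
  run_pipeline(list(seed = as.integer(seed)), out_dir)
}
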
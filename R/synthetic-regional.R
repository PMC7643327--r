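#' Specify a synthetic regional gradient dataset
#'
#' Defines a per-slice, per-region table of plaque burden and tracer influx
#' drawn around region means with gaussian within-region noise. The defaults
#' encode the dorsoventral pattern the clearance analysis is built to
#' detect: CSF-tracer influx highest ventrally (ventral > lateral > dorsal)
#' and plaque burden running the opposite way, so the population regression
#' of influx on burden has a negative slope by construction. Influx values
#' are in arbitrary background-subtracted intensity units; burden in
#' percent.
#'
#' @param n_slices Number of coronal slices (>= 2); default 7, one slice
#'   every five 100-um sections from 1 mm anterior to 2 mm posterior of
#'   bregma.
#' @param plaque_means `c(dorsal=, lateral=, ventral=)` burden means, pct.
#' @param influx_3k_means,influx_40k_means Region means for the two tracers,
#'   arbitrary units.
#' @param plaque_sd,influx_sd Within-region standard deviations.
#' @param seed Integer seed.
#' @return A `regional_gradient_spec` object.
#' @export
regional_gradient_spec <- function(n_slices = 7L,
                                   plaque_means = c(dorsal = 4, lateral = 2.5, ventral = 1),
                                   influx_3k_means = c(dorsal = 10, lateral = 20, ventral = 30),
                                   influx_40k_means = c(dorsal = 8, lateral = 16, ventral = 24),
                                   plaque_sd = 0.4,
                                   influx_sd = 2,
                                   seed = 1L) {
  if (n_slices < 2) abort("`n_slices` must be at least 2 (regression undefined).")
  for (m in list(plaque_means, influx_3k_means, influx_40k_means)) {
    if (!all(c("dorsal", "lateral", "ventral") %in% names(m)) ||
        any(!is.finite(m)) || any(m < 0)) {
      abort("region means must be finite, non-negative, named dorsal/lateral/ventral.")
    }
  }
  if (plaque_sd < 0 || influx_sd < 0) abort("noise sds must be non-negative.")
  structure(
    list(n_slices = as.integer(n_slices), plaque_means = plaque_means,
         influx_3k_means = influx_3k_means,
         influx_40k_means = influx_40k_means,
         plaque_sd = plaque_sd, influx_sd = influx_sd,
         seed = as.integer(seed)),
    class = "regional_gradient_spec"
  )
}

#' Generate a regional signal table from a gradient spec
#'
#' @param spec A [regional_gradient_spec()].
#' @return Tibble with one row per slice x region: `slice_id`, `region`,
#'   `plaque_burden`, `influx_3k`, `influx_40k`. Values are clipped at zero;
#'   the number of clipped draws is attached as attribute `n_clipped` (and a
#'   warning is raised when any draw is clipped).
#' @export
make_regional_dataset <- function(spec) {
  stopifnot(inherits(spec, "regional_gradient_spec"))
  regions <- c("dorsal", "lateral", "ventral")
  n <- spec$n_slices * length(regions)
  with_seed(spec$seed, {
    grid <- tibble(
      slice_id = rep(sprintf("slice%02d", seq_len(spec$n_slices)),
                     each = length(regions)),
      region = factor(rep(regions, spec$n_slices), levels = regions)
    )
    raw <- mutate(grid,
      plaque_burden = unname(spec$plaque_means[as.character(.data$region)]) +
        rnorm(n, sd = spec$plaque_sd),
      influx_3k = unname(spec$influx_3k_means[as.character(.data$region)]) +
        rnorm(n, sd = spec$influx_sd),
      influx_40k = unname(spec$influx_40k_means[as.character(.data$region)]) +
        rnorm(n, sd = spec$influx_sd)
    )
  })
  vals <- c(raw$plaque_burden, raw$influx_3k, raw$influx_40k)
  n_clipped <- sum(vals < 0)
  if (n_clipped > 0) {
    warn(paste0(n_clipped, " generated value(s) clipped at zero."))
  }
  out <- mutate(raw, across(c("plaque_burden", "influx_3k", "influx_40k"),
                            ~ pmax(.x, 0)))
  attr(out, "n_clipped") <- n_clipped
  attr(out, "spec") <- spec
  out
}

#' Generative burden-influx slope implied by a gradient spec
#'
#' Population least-squares slope of influx on burden under the spec's
#' generative model (region means hit with probability 1/3 each, plus
#' independent noise) — the oracle against which a fitted slope is compared.
#'
#' @param spec A [regional_gradient_spec()].
#' @param tracer `"influx_3k"` or `"influx_40k"`.
#' @return The population slope (a number).
#' @export
generative_slope <- function(spec, tracer = c("influx_3k", "influx_40k")) {
  tracer <- match.arg(tracer)
  mu_b <- spec$plaque_means
  mu_i <- if (tracer == "influx_3k") spec$influx_3k_means else spec$influx_40k_means
  cov_bi <- mean(mu_b * mu_i) - mean(mu_b) * mean(mu_i)
  var_b <- mean(mu_b^2) - mean(mu_b)^2 + spec$plaque_sd^2
  cov_bi / var_b
}
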
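#' Regression of CSF influx on amyloid burden
#'
#' Ordinary least squares of tracer influx on plaque burden over all
#' slice-by-region rows, the read-out used to relate amyloid load to
#' perivascular CSF entry (a negative slope indicates that influx falls
#' where burden is high). Rows from all regions and slices are pooled;
#' stratified fits per region are available via `stratify_by`.
#'
#' @param data A data frame with one row per observation, e.g. from
#'   [make_regional_dataset()] or (after filtering one channel) from
#'   [regional_table()].
#' @param influx Name of the influx column (default `"influx_3k"`).
#' @param burden Name of the burden column (default `"plaque_burden"`).
#' @param stratify_by Optional grouping column name; one fit per group.
#' @return For the pooled fit, an object of class `burden_influx_fit` with
#'   [tidy()], [glance()] and [autoplot()] methods. With `stratify_by`, a
#'   tibble of per-group [glance()] rows.
#' @examples
#' tbl <- make_regional_dataset(regional_gradient_spec(seed = 3))
#' fit <- burden_influx_regression(tbl)
#' glance(fit)
#' @export
burden_influx_regression <- function(data, influx = "influx_3k",
                                     burden = "plaque_burden",
                                     stratify_by = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(influx, burden)) {
    if (!col %in% names(data)) abort(paste0("column `", col, "` not found."))
  }
  if (!is.null(stratify_by)) {
    groups <- split(data, data[[stratify_by]])
    rows <- imap(groups, function(g, nm) {
      gl <- glance(burden_influx_regression(g, influx, burden))
      mutate(gl, "{stratify_by}" := nm, .before = 1)
    })
    return(bind_rows(rows))
  }
  keep <- is.finite(data[[influx]]) & is.finite(data[[burden]])
  d <- data.frame(influx = data[[influx]][keep], burden = data[[burden]][keep])
  if (nrow(d) < 3) abort("need at least 3 rows with finite burden and influx.")
  if (sd(d$burden) == 0) abort("zero variance in burden: regression undefined.")
  fit <- lm(influx ~ burden, data = d)
  structure(
    list(fit = fit, influx = influx, burden = burden, n = nrow(d), data = d),
    class = "burden_influx_fit"
  )
}

#' @export
print.burden_influx_fit <- function(x, ...) {
  g <- glance(x)
  cat("<burden-influx regression: ", x$influx, " ~ ", x$burden, ">\n", sep = "")
  cat(sprintf("  slope %.4g  intercept %.4g  R^2 %.3f  p %.3g  n %d\n",
              g$slope, g$intercept, g$r_squared, g$p_value, g$n))
  invisible(x)
}

#' @rdname burden_influx_regression
#' @param x A `burden_influx_fit`.
#' @param ... Unused.
#' @export
tidy.burden_influx_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", x$burden),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname burden_influx_regression
#' @export
glance.burden_influx_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    slope = co[2, 1],
    intercept = co[1, 1],
    slope_se = co[2, 2],
    r_squared = s$r.squared,
    p_value = co[2, 4],
    residual_sd = s$sigma,
    n = x$n,
    slope_sign = sign(co[2, 1])
  )
}

#' Per-group summary table (mean, SEM, n)
#'
#' Prepares per-group descriptive statistics and a long-format table ready
#' for external inferential analysis (e.g. two-way ANOVA on genotype and
#' age); no hypothesis testing is performed here.
#'
#' @param data A data frame.
#' @param ... Grouping columns (tidy-select, passed to [dplyr::group_by()]),
#'   e.g. `vessel_type`, `caa`, `region`.
#' @param value Name of the value column to summarize.
#' @return Tibble with one row per group: grouping columns, `mean`, `sd`,
#'   `sem`, `n`. Rows with missing values are dropped with a warning.
#' @export
group_summary <- function(data, ..., value) {
  if (!value %in% names(data)) abort(paste0("column `", value, "` not found."))
  miss <- !is.finite(data[[value]])
  if (any(miss)) {
    warn(paste0(sum(miss), " row(s) with missing `", value, "` dropped."))
    data <- data[!miss, , drop = FALSE]
  }
  data |>
    group_by(...) |>
    summarise(
      mean = mean(.data[[value]]),
      sd = sd(.data[[value]]),
      sem = sd(.data[[value]]) / sqrt(n()),
      n = n(),
      .groups = "drop"
    )
}
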
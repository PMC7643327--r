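#' Threshold policies
#'
#' Intensity thresholds in the pipeline are expressed as small policy objects
#' so that the resolved numeric value can always be recorded alongside the
#' result. Three policies are provided: a fixed value (required when
#' comparability across images matters, as with a constant plaque threshold
#' applied to a whole cohort), Otsu's method (per-image, parameter-free), and
#' a quantile of the pixel distribution.
#'
#' @param value Numeric threshold on the intensity scale of the image.
#' @param p Quantile in `[0, 1]`.
#' @return A policy object of class `pvq_threshold`.
#' @examples
#' resolve_threshold(threshold_fixed(0.3), runif(100))
#' resolve_threshold(threshold_quantile(0.9), runif(100))
#' @name threshold_policy
NULL

#' @rdname threshold_policy
#' @export
threshold_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(method = "fixed", value = value), class = "pvq_threshold")
}

#' @rdname threshold_policy
#' @export
threshold_otsu <- function() {
  structure(list(method = "otsu"), class = "pvq_threshold")
}

#' @rdname threshold_policy
#' @export
threshold_quantile <- function(p = 0.95) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  structure(list(method = "quantile", p = p), class = "pvq_threshold")
}

#' Resolve a threshold policy against pixel intensities
#'
#' @param policy A `pvq_threshold` object (a bare number is promoted to a
#'   fixed policy).
#' @param x Numeric vector or matrix of intensities the policy is resolved
#'   against (ignored for fixed policies).
#' @return The resolved numeric threshold.
#' @export
resolve_threshold <- function(policy, x = NULL) {
  if (is.numeric(policy) && length(policy) == 1L) policy <- threshold_fixed(policy)
  if (!inherits(policy, "pvq_threshold")) {
    abort("`policy` must be a pvq_threshold object or a single number.")
  }
  switch(policy$method,
    fixed = policy$value,
    quantile = {
      if (is.null(x)) abort("quantile threshold needs pixel data to resolve.")
      unname(quantile(as.numeric(x), policy$p, na.rm = TRUE))
    },
    otsu = {
      if (is.null(x)) abort("Otsu threshold needs pixel data to resolve.")
      v <- as.numeric(x)
      v <- v[is.finite(v)]
      rng <- range(v)
      if (diff(rng) == 0) return(rng[1]) # flat image: everything at the value
      EBImage::otsu(matrix(v, nrow = 1L), range = rng, levels = 256L)
    }
  )
}

#' @export
print.pvq_threshold <- function(x, ...) {
  cat("<threshold policy:", x$method,
      if (x$method == "fixed") paste0("value=", x$value),
      if (x$method == "quantile") paste0("p=", x$p), ">\n")
  invisible(x)
}
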
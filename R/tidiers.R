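# broom-style tidiers for the package's fitted objects

#' Tidy a biexponential FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("bleach_depth", "a1", "k1", "a2", "k2"),
    estimate = c(x$bleach_depth_fitted, x$a1, x$k1, x$a2, x$k2)
  )
}

#' @rdname tidy.frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    mobile_fraction = x$mobile_fraction, t_half = x$t_half,
    rss = x$rss, n_points = x$n_points,
    immobile = x$immobile, over_recovery = x$over_recovery
  )
}

#' Tidy a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`, `std.error` where
#'   available).
#' @export
tidy.binding_fit <- function(x, ...) {
  if (x$mode == "fluorescence") {
    tibble(
      term = c("kd", "response_free", "response_sat"),
      estimate = c(x$kd, x$response_free, x$response_sat),
      std.error = c(x$standard_error_kd, NA_real_, NA_real_)
    )
  } else {
    tibble(
      term = c("kd", paste0("amplitude_", names(x$amplitudes))),
      estimate = c(x$kd, unname(x$amplitudes)),
      std.error = c(x$standard_error_kd, rep(NA_real_, length(x$amplitudes)))
    )
  }
}

#' @rdname tidy.binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(
    kd = x$kd, standard_error_kd = x$standard_error_kd, rss = x$rss,
    mode = x$mode, n_points = x$n_points,
    misfit = x$misfit %||% FALSE
  )
}

#' Tidy a cohort comparison
#'
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @export
tidy.cohort_comparison <- function(x, ...) x$summary

#' @rdname tidy.cohort_comparison
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value)
}

#' Tidy a multivalence result
#'
#' @param x A `multivalence_result`.
#' @param ... Unused.
#' @return The per-bin profile tibble (`bin`, `percentile_mid`,
#'   `ratio`, relative enrichments).
#' @export
tidy.multivalence_result <- function(x, ...) x$profile

#' @rdname tidy.multivalence_result
#' @export
glance.multivalence_result <- function(x, ...) {
  tibble(
    index = x$index, p_value = x$p_value,
    null_lower = x$null_band[1], null_upper = x$null_band[2],
    multivalent = x$multivalent,
    n_bins = x$n_bins, n_perm = x$n_perm
  )
}
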
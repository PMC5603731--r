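# ggplot2 visualisations of the package's result types

#' Plot a normalized FRAP trace with its biexponential fit
#'
#' @param object A `normalized_trace`.
#' @param fit Optional `frap_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_trace <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_post, y = .data$recovery)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized recovery")
  if (!is.null(fit)) {
    post <- object[object$phase == "post", ]
    t <- seq(0, max(post$time_post), length.out = 400)
    curve <- tibble(
      time_post = t,
      recovery = .biexp(t, fit$bleach_depth_fitted, fit$a1, fit$k1, fit$a2, fit$k2)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick", linewidth = 0.8)
    if (!is.na(fit$t_half)) {
      p <- p + ggplot2::geom_vline(xintercept = fit$t_half, linetype = "dashed")
    }
  }
  p
}

#' Plot a titration and its binding-isotherm fit
#'
#' @param object A `titration_series` (fluorescence mode).
#' @param fit Optional `binding_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.titration_series <- function(object, fit = NULL, ...) {
  if (attr(object, "mode") == "nmr_csp") {
    p <- ggplot2::ggplot(object, ggplot2::aes(
      x = .data$ligand_uM, y = .data$csp, colour = .data$residue
    )) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "ligand (uM)", y = "combined CSP (ppm)")
    return(p)
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$ligand_uM, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ligand (uM)", y = "response (a.u.)")
  if (!is.null(fit)) {
    L <- seq(min(object$ligand_uM), max(object$ligand_uM), length.out = 300)
    P <- if (fit$model == "hyperbolic") 0 else fit$protein_uM
    curve <- tibble(
      ligand_uM = L,
      response = fit$response_free +
        (fit$response_sat - fit$response_free) * fraction_bound(P, L, fit$kd)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}

#' Plot the relative-enrichment profile of a multivalence analysis
#'
#' Reproduces the ratio-vs-percentile view: each signal's per-bin mean,
#' normalized to its own maximum bin mean, across H3K4me3 percentile
#' bins. A flat reader/reference ratio indicates monovalent reading.
#'
#' @param object A `multivalence_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multivalence_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profile,
    dplyr::starts_with("rel_"),
    names_to = "signal", values_to = "relative_enrichment",
    names_prefix = "rel_"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$percentile_mid, y = .data$relative_enrichment,
    colour = .data$signal
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = sprintf("%s percentile", object$k4),
      y = "relative enrichment (bin mean / max bin mean)",
      subtitle = sprintf(
        "multivalence index %.2f (null band [%.2f, %.2f])",
        object$index, object$null_band[1], object$null_band[2]
      )
    )
}

#' Plot a metaprofile
#'
#' @param object A `metaprofile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metaprofile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from anchor (bp)", y = "mean signal")
}

#' Boxplot of per-cell half recovery times by cohort
#'
#' @param object A `cohort_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$group, y = .data$t_half)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = expression(t[1 / 2] ~ "(s)"),
      subtitle = sprintf("Student's t test: p = %.3g", object$p_value)
    )
}
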
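#' Construct a FRAP trace from raw columns
#'
#' Validates and packages a single-cell FRAP time series (bleach-spot and
#' whole-cell channels) for the analysis chain. Most users will obtain
#' traces from [simulate_frap_trace()] or read them from TSV with
#' [read_frap_trace()].
#'
#' @param data Data frame with columns `time` (s, strictly increasing),
#'   `roi_intensity`, `cell_intensity`, and optionally `background`
#'   (default 0).
#' @param bleach_index 1-based index of the first post-bleach frame;
#'   at least 2 pre-bleach frames must precede it.
#' @return A tibble of class `frap_trace`.
#' @export
frap_trace <- function(data, bleach_index) {
  stopifnot(is.data.frame(data))
  need <- c("time", "roi_intensity", "cell_intensity")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns ", paste(need, collapse = ", "), "."))
  }
  if (!"background" %in% names(data)) data$background <- 0
  if (any(diff(data$time) <= 0)) abort("`time` must be strictly increasing.")
  bleach_index <- check_count(bleach_index, "bleach_index", min = 3L)
  if (bleach_index > nrow(data)) abort("`bleach_index` is out of range.")
  out <- as_tibble(data[, c("time", "roi_intensity", "cell_intensity", "background")])
  structure(out,
    bleach_index = bleach_index,
    class = c("frap_trace", class(out))
  )
}

#' Double-normalize a FRAP trace
#'
#' Normalizes a trace for the initial conditions (brightness of the cell
#' and of the bleached spot) and corrects acquisition photobleaching:
#' after background subtraction, the spot/whole-cell ratio is divided by
#' its pre-bleach mean, so the pre-bleach level is 1 by construction and
#' any photobleaching shared by the two channels cancels.
#'
#' @param trace A [frap_trace()] (or any data frame with the same columns
#'   plus a `bleach_index` attribute or argument).
#' @param bleach_index Optional override of the trace's bleach index.
#' @return A tibble of class `normalized_trace` with columns `time`,
#'   `time_post` (s, zero at the first post-bleach frame), `recovery`,
#'   and `phase` (`"pre"`/`"post"`); `bleach_index` is kept as an
#'   attribute.
#' @examples
#' tr <- simulate_frap_trace(frap_sim_params(seed = 2))
#' nt <- normalize_trace(tr)
#' mean(nt$recovery[nt$phase == "pre"]) # 1
#' @export
normalize_trace <- function(trace, bleach_index = NULL) {
  bleach_index <- bleach_index %||% attr(trace, "bleach_index")
  if (is.null(bleach_index)) abort("`bleach_index` is required.")
  tr <- frap_trace(as.data.frame(trace), bleach_index)

  roi <- tr$roi_intensity - tr$background
  cell <- tr$cell_intensity - tr$background
  if (any(cell <= 0)) {
    abort("Whole-cell intensity is not positive after background subtraction; check segmentation/background.")
  }
  ratio <- roi / cell
  pre <- seq_len(bleach_index - 1L)
  recovery <- ratio / mean(ratio[pre])
  if (any(!is.finite(recovery))) abort("Non-finite recovery values produced.")

  out <- tibble(
    time = tr$time,
    time_post = tr$time - tr$time[bleach_index],
    recovery = recovery,
    phase = ifelse(seq_len(nrow(tr)) < bleach_index, "pre", "post")
  )
  structure(out,
    bleach_index = bleach_index,
    class = c("normalized_trace", class(out))
  )
}

# biexponential recovery model on post-bleach time
.biexp <- function(t, b, a1, k1, a2, k2) {
  b + a1 * (1 - exp(-k1 * t)) + a2 * (1 - exp(-k2 * t))
}

#' Fit a biexponential recovery to a normalized FRAP trace
#'
#' Least-squares fit of
#' `recovery(t) = b + a1 (1 - exp(-k1 t)) + a2 (1 - exp(-k2 t))`
#' to the post-bleach frames, where `b` is the fitted bleach depth and
#' `a1 + a2` the mobile amplitude. Because biexponential fits are
#' initialization-sensitive, the fit is multi-started over distinct rate
#' pairs drawn from \{100, 10, 1, 0.1\} / t_range with the linear parameters
#' (`b`, `a1`, `a2`) obtained by projection at each start; the refined
#' fit with the lowest residual sum of squares wins, ties broken in
#' favour of the smaller `k1 / k2` ratio. Components are returned with
#' `k1 >= k2`.
#'
#' @param norm A [normalize_trace()] result (>= 20 post-bleach frames).
#' @param over_recovery_tol Plateaus above `1 + 3 * noise` trigger an
#'   over-recovery flag; `noise` is the post-fit residual sd.
#' @return An object of class `frap_fit`: `a1`, `a2`, `k1`, `k2`,
#'   `bleach_depth_fitted`, `mobile_fraction`
#'   (`(a1 + a2) / (1 - b)`, the recovered share of the bleached
#'   amount), `t_half` (s, via [half_time()]; `NA` with a flag when the
#'   trace is immobile), `rss`, `n_points`, and logical flags
#'   `immobile`, `over_recovery`.
#' @export
fit_biexponential <- function(norm, over_recovery_tol = 3) {
  stopifnot(inherits(norm, "normalized_trace") || is.data.frame(norm))
  post <- norm[norm$phase == "post", , drop = FALSE]
  t <- post$time_post
  y <- post$recovery
  if (length(t) < 20) abort("At least 20 post-bleach points are required.")

  t_range <- max(t)
  ks <- c(100, 10, 1, 0.1) / t_range
  starts <- list()
  for (i in seq_along(ks)) {
    for (j in seq_along(ks)) {
      if (i < j) starts[[length(starts) + 1L]] <- c(ks[i], ks[j])
    }
  }

  project <- function(k1, k2) {
    X <- cbind(1, 1 - exp(-k1 * t), 1 - exp(-k2 * t))
    co <- stats::lm.fit(X, y)$coefficients
    co[!is.finite(co)] <- 0
    # keep amplitude starts well away from zero: a vanishing amplitude
    # zeroes the Jacobian column of its rate and stalls the optimizer
    c(min(max(co[1], 0), 1), max(co[2], 0.05), max(co[3], 0.05))
  }

  best <- NULL
  diagnostics <- list()
  for (st in starts) {
    co0 <- project(st[1], st[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .biexp(t, b, a1, exp(lk1), a2, exp(lk2)),
        start = list(
          b = unname(co0[1]), a1 = unname(co0[2]), lk1 = log(st[1]),
          a2 = unname(co0[3]), lk2 = log(st[2])
        ),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      diagnostics[[length(diagnostics) + 1L]] <- list(start = st, error = TRUE)
      next
    }
    co <- coef(fit)
    cand <- list(
      b = co[["b"]], a1 = co[["a1"]], k1 = exp(co[["lk1"]]),
      a2 = co[["a2"]], k2 = exp(co[["lk2"]]), rss = deviance(fit)
    )
    if (is.null(best) ||
      cand$rss < best$rss - 1e-12 ||
      (abs(cand$rss - best$rss) <= 1e-12 &&
        max(cand$k1, cand$k2) / min(cand$k1, cand$k2) <
          max(best$k1, best$k2) / min(best$k1, best$k2))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    abort("Biexponential fit failed to converge from all starts.",
      class = "chromvalence_fit_error"
    )
  }

  # order components so k1 >= k2
  if (best$k1 < best$k2) {
    best[c("a1", "k1", "a2", "k2")] <- best[c("a2", "k2", "a1", "k1")]
  }
  noise <- sqrt(best$rss / max(length(t) - 5, 1))
  plateau <- best$b + best$a1 + best$a2
  mobile <- (best$a1 + best$a2) / max(1 - best$b, .Machine$double.eps)
  immobile <- (best$a1 + best$a2) < max(3 * noise, 1e-6)

  out <- structure(
    list(
      a1 = best$a1, a2 = best$a2, k1 = best$k1, k2 = best$k2,
      bleach_depth_fitted = best$b,
      mobile_fraction = mobile,
      rss = best$rss,
      n_points = length(t),
      immobile = immobile,
      over_recovery = plateau > 1 + over_recovery_tol * noise,
      t_half = NA_real_
    ),
    class = "frap_fit"
  )
  if (!immobile) out$t_half <- half_time(out)
  out
}

#' Half recovery time of a biexponential fit
#'
#' Returns the unique time at which the mobile recovery
#' `a1 (1 - exp(-k1 t)) + a2 (1 - exp(-k2 t))` reaches half of its
#' plateau `a1 + a2`, found by bisection to a relative tolerance of
#' 1e-9. The half-point is measured above the fitted bleach depth, so it
#' is invariant both to the immobile fraction and to rescaling the
#' amplitudes. Uniqueness follows from strict monotonicity of the
#' recovery.
#'
#' @param fit A `frap_fit`, or any list with fields `a1`, `k1`, `a2`,
#'   `k2`.
#' @return Half recovery time in seconds.
#' @examples
#' half_time(list(a1 = 1, a2 = 0, k1 = log(2), k2 = 1)) # 1
#' @export
half_time <- function(fit) {
  a1 <- fit$a1
  a2 <- fit$a2
  k1 <- fit$k1
  k2 <- fit$k2
  if (a1 + a2 <= 0) abort("Half time undefined: mobile amplitude is not positive.")
  if (k1 <= 0 || k2 <= 0) abort("Rates must be positive.")
  target <- (a1 + a2) / 2
  f <- function(t) a1 * (1 - exp(-k1 * t)) + a2 * (1 - exp(-k2 * t)) - target
  hi <- 1 / max(k1, k2)
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-9 * hi) break
  }
  (lo + hi) / 2
}

#' Compare half-recovery times between two cohorts of cells
#'
#' Two-sided Student's t test (equal variances) on per-cell half
#' recovery times, with the boxplot summary statistics (median, IQR)
#' reported per group.
#'
#' @param data Data frame with columns `group` (exactly two levels, each
#'   with >= 2 cells) and `t_half` (s), one row per cell. A named list of
#'   two numeric vectors is also accepted.
#' @return An object of class `cohort_comparison`: the `p_value`, the
#'   t statistic, and a `summary` tibble (group, n, mean, median, q1,
#'   q3). `tidy()`/`glance()` methods are provided.
#' @export
compare_cohorts <- function(data) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble(
      group = rep(names(data), lengths(data)),
      t_half = unlist(data, use.names = FALSE)
    )
  }
  stopifnot(is.data.frame(data), all(c("group", "t_half") %in% names(data)))
  groups <- unique(data$group)
  if (length(groups) != 2) abort("Exactly two groups are required.")
  split_vals <- split(data$t_half, factor(data$group, levels = groups))
  if (any(lengths(split_vals) < 2)) abort("Each group needs at least 2 cells.")
  if (all(purrr::map_dbl(split_vals, stats::var) == 0)) {
    abort("Both groups have zero variance; the t test is undefined.")
  }
  tt <- t.test(split_vals[[1]], split_vals[[2]], var.equal = TRUE)
  summary_tbl <- dplyr::group_by(data, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$t_half),
      median = median(.data$t_half),
      q1 = quantile(.data$t_half, 0.25)[[1]],
      q3 = quantile(.data$t_half, 0.75)[[1]],
      .groups = "drop"
    )
  structure(
    list(
      groups = as.character(groups),
      p_value = tt$p.value,
      statistic = unname(tt$statistic),
      summary = summary_tbl,
      data = as_tibble(data)
    ),
    class = "cohort_comparison"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> b=%.3f a1=%.3f k1=%.3g a2=%.3f k2=%.3g  mobile=%.3f  t1/2=%s s\n",
    x$bleach_depth_fitted, x$a1, x$k1, x$a2, x$k2, x$mobile_fraction,
    ifelse(is.na(x$t_half), "NA", sprintf("%.3f", x$t_half))
  ))
  if (x$immobile) cat("  flag: immobile (no resolvable mobile amplitude)\n")
  if (x$over_recovery) cat("  flag: over-recovery (plateau above pre-bleach level)\n")
  invisible(x)
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf(
    "<cohort_comparison> %s vs %s: t = %.3f, p = %.3g\n",
    x$groups[1], x$groups[2], x$statistic, x$p_value
  ))
  print(x$summary)
  invisible(x)
}
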
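#' Equal-population percentile bins of an enrichment matrix column
#'
#' Ranks intervals by one signal column and assigns them to `n_bins`
#' bins of (as near as possible) equal population — bin sizes differ by
#' at most one. Ordering is by the stable sort order of the key, so tied
#' values falling on a bin boundary are split in input order; the
#' reported percentile uses average ranks so ties share a percentile.
#'
#' @param matrix Data frame with one row per interval and named signal
#'   columns (an "enrichment matrix" as produced by
#'   [quantify_intervals()] outputs joined per signal).
#' @param key Name of the column to bin on.
#' @param n_bins Number of bins (>= 2).
#' @return The input tibble with added columns `percentile` (average
#'   rank as a 0-100 percentile) and `bin` (1 = lowest key values).
#' @examples
#' m <- data.frame(h3k4me3 = c(1, 1, 2, 3))
#' percentile_bins(m, "h3k4me3", 2)$bin # 1 1 2 2
#' @export
percentile_bins <- function(matrix, key, n_bins) {
  stopifnot(is.data.frame(matrix))
  if (!key %in% names(matrix)) abort(sprintf("Column `%s` not found.", key))
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  v <- matrix[[key]]
  if (any(!is.finite(v))) abort(sprintf("`%s` contains non-finite values.", key))
  n <- length(v)
  if (length(unique(v)) == 1) {
    abort("All key values are equal; percentiles are undefined.")
  }
  if (n < n_bins) abort("Fewer intervals than bins.")
  ord <- order(v) # stable: ties keep input order
  bin <- integer(n)
  bin[ord] <- floor((seq_len(n) - 1) * n_bins / n) + 1L
  out <- as_tibble(matrix)
  out$percentile <- 100 * (rank(v, ties.method = "average") - 0.5) / n
  out$bin <- bin
  out
}

#' Divergence-from-linearity multivalence index
#'
#' Quantifies whether a chromatin reader's occupancy scales with
#' non-methylated DNA alone (monovalent reading) or is boosted at
#' H3K4me3-rich islands (multivalent reading). Intervals are binned into
#' `n_bins` equal-population H3K4me3 percentile bins
#' ([percentile_bins()]); per bin the ratio
#' `r_b = mean(signal) / mean(reference)` is computed; the index is the
#' Spearman rank correlation between bin rank and `r_b`. A purely
#' monovalent reader gives a flat ratio profile and an index near 0; a
#' multivalent reader gives a ratio that increases with the H3K4me3
#' percentile and an index near 1.
#'
#' Significance is calibrated by permutation: the H3K4me3 bin
#' assignments are shuffled across intervals while each interval keeps
#' its own (reference, signal) pair — so the signal-reference coupling
#' (including any shared background) is preserved exactly while the
#' H3K4me3 association is broken — and the index is recomputed `n_perm`
#' times. The multivalence call uses the exact permutation p-value
#' `(1 + #permuted |index| >= observed |index|) / (n_perm + 1)`
#' against `alpha` (guaranteeing a type-I rate of at most `alpha` under
#' exchangeability); the `c(alpha/2, 1 - alpha/2)` quantile band of the
#' null distribution is also reported for display.
#'
#' @param matrix Data frame with one row per interval and the named
#'   signal columns; needs at least `5 * n_bins` intervals.
#' @param signal Column holding the reader occupancy to test.
#' @param reference Column holding the non-methylated DNA signal
#'   (default `"biocap"`); must have a positive mean in every bin.
#' @param k4 Column holding the H3K4me3 signal (default `"h3k4me3"`).
#' @param n_bins Number of percentile bins (default 20).
#' @param n_perm Number of permutations for the null band
#'   (default 200).
#' @param alpha Two-sided tail mass outside the null band (default
#'   0.02, i.e. the central 98% interval of the permutation
#'   distribution, keeping the false-flag rate on genuinely monovalent
#'   data comfortably low).
#' @return An object of class `multivalence_result`: `index`,
#'   `p_value` (exact permutation p-value on |index|), `null_band`
#'   (length-2), `null_indices`, `multivalent` (logical:
#'   `p_value <= alpha`), `profile` (tibble: `bin`,
#'   `percentile_mid`, `ratio`, and one `rel_<signal>` column per
#'   signal, each bin mean normalized to that signal's maximum bin
#'   mean), and the call parameters.
#' @export
multivalence_index <- function(matrix, signal, reference = "biocap",
                               k4 = "h3k4me3", n_bins = 20, n_perm = 200,
                               alpha = 0.02) {
  stopifnot(is.data.frame(matrix))
  for (col in c(signal, reference, k4)) {
    if (!col %in% names(matrix)) abort(sprintf("Column `%s` not found.", col))
  }
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  if (nrow(matrix) < 5 * n_bins) {
    abort(sprintf("At least %d intervals are required for %d bins.", 5 * n_bins, n_bins))
  }
  binned <- percentile_bins(matrix, k4, n_bins)

  index_of <- function(bin_assign) {
    ms <- tapply(binned[[signal]], bin_assign, mean)
    mr <- tapply(binned[[reference]], bin_assign, mean)
    if (any(mr == 0)) {
      abort("A percentile bin has zero mean reference signal; the ratio is undefined.")
    }
    r_b <- ms / mr
    # an exactly proportional signal gives a flat ratio profile whose
    # ranks are pure floating-point noise; report 0, not an arbitrary rank
    if (diff(range(r_b)) <= 1e-9 * mean(abs(r_b))) {
      return(0)
    }
    cor(seq_len(n_bins), r_b, method = "spearman")
  }
  index <- index_of(binned$bin)

  # null: shuffle which bin each interval belongs to, keeping every
  # interval's own (reference, signal) pair — the signal-reference
  # coupling survives intact and only the H3K4me3 ordering is broken
  null_indices <- purrr::map_dbl(seq_len(n_perm), function(i) {
    index_of(sample(binned$bin))
  })
  null_band <- unname(quantile(null_indices, c(alpha / 2, 1 - alpha / 2)))
  p_value <- (1 + sum(abs(null_indices) >= abs(index))) / (n_perm + 1)

  # relative-enrichment profile: per-bin means normalized to each
  # signal's maximum bin mean (all signal columns present)
  num_cols <- names(matrix)[purrr::map_lgl(matrix, is.numeric)]
  num_cols <- setdiff(num_cols, c("start", "end", "percentile", "bin"))
  profile <- tibble(
    bin = sort(unique(binned$bin)),
    percentile_mid = as.numeric(tapply(binned$percentile, binned$bin, mean))
  )
  mr <- tapply(binned[[reference]], binned$bin, mean)
  profile$ratio <- as.numeric(tapply(binned[[signal]], binned$bin, mean)) / as.numeric(mr)
  for (col in num_cols) {
    m <- as.numeric(tapply(binned[[col]], binned$bin, mean))
    profile[[paste0("rel_", col)]] <- m / max(m)
  }

  structure(
    list(
      index = index, p_value = p_value,
      null_band = null_band, null_indices = null_indices,
      multivalent = p_value <= alpha,
      profile = profile,
      signal = signal, reference = reference, k4 = k4,
      n_bins = n_bins, n_perm = n_perm, alpha = alpha,
      n = nrow(binned)
    ),
    class = "multivalence_result"
  )
}

#' @export
print.multivalence_result <- function(x, ...) {
  cat(sprintf(
    "<multivalence_result> %s vs %s across %s percentiles: index = %.3f, permutation p = %.4g, null band [%.3f, %.3f] -> %s\n",
    x$signal, x$reference, x$k4, x$index, x$p_value, x$null_band[1], x$null_band[2],
    if (x$multivalent) "multivalent" else "consistent with monovalent reading"
  ))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Spearman's rho with average-rank tie handling; errors on constant
#' input, where ranks are undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho in \[-1, 1\].
#' @examples
#' rank_correlation(1:4, c(1, 3, 2, 4)) # 0.8
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("At least 3 observations are required.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Rank correlation is undefined for constant input.")
  }
  cor(x, y, method = "spearman")
}
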
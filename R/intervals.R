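# interval analytics over BED-dialect records (0-based, half-open)

as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

validate_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df))
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    abort(sprintf("`%s` needs columns chrom, start, end.", what))
  }
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    abort(sprintf("`%s` must satisfy start < end (0-based, half-open).", what))
  }
  as_tibble(df)
}

#' Two-way overlap statistics between peaks and NMIs
#'
#' Venn-style overlap summary between two interval sets (e.g. reader
#' ChIP peaks and non-methylated islands): how many intervals of each
#' set intersect at least 1 bp of the other, with fractions relative to
#' each set's own total. The asymmetry of the two fractions is the
#' informative quantity — a reader can sit almost exclusively on islands
#' while occupying only a minority of them.
#'
#' @param peaks,nmis Data frames with `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @return A tibble of class `overlap_venn` with one row per set
#'   (`set`, `n`, `n_overlapping`, `n_only`, `fraction_overlapping`).
#'   Empty input sets report `NA` fractions rather than 0.
#' @examples
#' overlap_venn(
#'   data.frame(chrom = "c", start = c(0, 20, 50), end = c(10, 30, 60)),
#'   data.frame(chrom = "c", start = c(5, 25), end = c(15, 35))
#' )
#' @export
overlap_venn <- function(peaks, nmis) {
  peaks <- validate_intervals(peaks, "peaks")
  nmis <- validate_intervals(nmis, "nmis")
  count_hit <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) {
      return(0L)
    }
    sum(IRanges::overlapsAny(as_granges0(a), as_granges0(b)))
  }
  p_hit <- count_hit(peaks, nmis)
  n_hit <- count_hit(nmis, peaks)
  out <- tibble(
    set = c("peaks", "nmis"),
    n = c(nrow(peaks), nrow(nmis)),
    n_overlapping = c(p_hit, n_hit),
    n_only = c(nrow(peaks) - p_hit, nrow(nmis) - n_hit),
    fraction_overlapping = c(
      if (nrow(peaks) > 0) p_hit / nrow(peaks) else NA_real_,
      if (nrow(nmis) > 0) n_hit / nrow(nmis) else NA_real_
    )
  )
  class(out) <- c("overlap_venn", class(out))
  out
}

#' Cross-tabulate TSS overlap for bound vs unbound intervals
#'
#' For a set of NMIs carrying a logical `bound` column (reader-occupied
#' or not), counts how many in each class contain at least one
#' transcription start site. An NMI "contains" a TSS when the TSS point
#' falls inside the interval extended by `window` bp on each side
#' (half-open: a TSS at the interval end does not count).
#'
#' @param intervals Data frame with `chrom`, `start`, `end`, `bound`
#'   (logical).
#' @param tss Data frame with `chrom`, `pos` (0-based point).
#' @param window Symmetric extension in bp (default 0); clipped at
#'   chromosome start.
#' @return A tibble with one row per class (`bound`, `n`,
#'   `n_with_tss`, `percent_with_tss`).
#' @export
annotate_tss <- function(intervals, tss, window = 0) {
  intervals <- validate_intervals(intervals, "intervals")
  if (!"bound" %in% names(intervals)) {
    abort("`intervals` needs a logical `bound` column.")
  }
  stopifnot(is.data.frame(tss), all(c("chrom", "pos") %in% names(tss)))
  check_scalar(window, "window", 0)
  iv <- tibble(
    chrom = intervals$chrom,
    start = pmax(intervals$start - window, 0),
    end = intervals$end + window
  )
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(start = tss$pos + 1, width = 1)
  )
  has_tss <- IRanges::overlapsAny(as_granges0(iv), tss_gr)
  tibble(bound = intervals$bound, has_tss = has_tss) |>
    dplyr::group_by(.data$bound) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_with_tss = sum(.data$has_tss),
      percent_with_tss = 100 * mean(.data$has_tss),
      .groups = "drop"
    )
}

#' Average signal profile around anchor points
#'
#' Metaprofile (metagene/metaplot) of a binned signal track across a set
#' of stranded anchor points such as TSSs: the window
#' `[anchor - flank, anchor + flank)` is divided into `n_bins`
#' equal-width profile bins, each anchor contributes the
#' overlap-weighted mean track value per profile bin, minus-strand
#' profiles are reversed before averaging, and the per-bin mean over
#' anchors is returned. Anchors whose window lies entirely outside the
#' track's coverage are excluded and counted.
#'
#' @param track Data frame with `chrom`, `start`, `end`, `value`.
#' @param anchors Data frame with `chrom`, `pos` and optionally `strand`
#'   (`"+"`/`"-"`, default `"+"`).
#' @param flank Half-window in bp (> 0).
#' @param n_bins Number of profile bins (even split of the window).
#' @return A tibble of class `metaprofile`: `bin` (1..n_bins),
#'   `position` (bin-center offset from the anchor, bp; negative =
#'   upstream in anchor orientation), `mean_signal`, `n_anchors`.
#'   Attribute `n_excluded` counts anchors dropped for lying outside
#'   coverage.
#' @export
metaprofile <- function(track, anchors, flank, n_bins = 50) {
  track <- validate_track(track)
  stopifnot(is.data.frame(anchors), all(c("chrom", "pos") %in% names(anchors)))
  check_scalar(flank, "flank", 0, open_lower = TRUE)
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  strand <- if ("strand" %in% names(anchors)) {
    anchors$strand
  } else {
    rep("+", nrow(anchors))
  }

  bin_w <- 2 * flank / n_bins
  cov_lo <- min(track$start)
  cov_hi <- max(track$end)

  # all anchor x profile-bin windows as one interval set, then a single
  # overlap-weighted quantification pass
  n_a <- nrow(anchors)
  grid <- tibble(
    anchor = rep(seq_len(n_a), each = n_bins),
    bin = rep(seq_len(n_bins), times = n_a),
    chrom = rep(anchors$chrom, each = n_bins)
  )
  grid$start <- anchors$pos[grid$anchor] - flank + (grid$bin - 1) * bin_w
  grid$end <- grid$start + bin_w

  window_outside <- tapply(
    grid$end <= cov_lo | grid$start >= cov_hi, grid$anchor, all
  )
  keep_anchor <- which(!window_outside)
  n_excluded <- n_a - length(keep_anchor)

  grid <- grid[grid$anchor %in% keep_anchor, , drop = FALSE]
  grid$start <- pmax(grid$start, 0)
  grid <- grid[grid$end > grid$start, , drop = FALSE]
  if (nrow(grid) == 0) abort("No anchor window overlaps the track.")
  q <- quantify_intervals(track, grid[, c("chrom", "start", "end")])

  oriented_bin <- ifelse(strand[grid$anchor] == "-",
    n_bins + 1L - grid$bin, grid$bin
  )
  contrib <- tibble(bin = oriented_bin, value = q$mean_signal, covered = q$covered)
  agg <- contrib |>
    dplyr::filter(.data$covered) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_signal = mean(.data$value), n_anchors = dplyr::n(),
      .groups = "drop"
    )

  out <- tibble(bin = seq_len(n_bins)) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::mutate(
      position = -flank + (.data$bin - 0.5) * bin_w,
      mean_signal = ifelse(is.na(.data$mean_signal), 0, .data$mean_signal),
      n_anchors = ifelse(is.na(.data$n_anchors), 0L, .data$n_anchors)
    ) |>
    dplyr::select("bin", "position", "mean_signal", "n_anchors")
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("metaprofile", class(out))
  out
}

#' Call islands from a continuous signal track by threshold-and-merge
#'
#' Utility for synthetic data: bins with signal above `threshold` are
#' kept, runs separated by gaps shorter than `gap_max` bp are merged,
#' and islands narrower than `min_width` bp are dropped. Real NMI/CGI
#' calls should be supplied as BED input; this is not a peak caller.
#'
#' @param track Data frame with `chrom`, `start`, `end`, `value`.
#' @param threshold Minimum bin signal.
#' @param gap_max Merge gaps strictly smaller than this (bp).
#' @param min_width Minimum island width (bp).
#' @return A tibble of intervals (`chrom`, `start`, `end`, `name`).
#' @export
call_islands <- function(track, threshold, gap_max = 0, min_width = 0) {
  track <- validate_track(track)
  keep <- track[track$value > threshold, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      name = character()
    ))
  }
  gr <- GenomicRanges::reduce(as_granges0(keep), min.gapwidth = max(gap_max, 1))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  out <- out[out$end - out$start >= min_width, , drop = FALSE]
  out$name <- sprintf("island_%04d", seq_len(nrow(out)))
  out
}
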
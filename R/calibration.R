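#' Spike-in calibration factors from read summaries
#'
#' Computes one multiplicative calibration factor per sample from
#' spike-genome read totals: `alpha = 1e6 / spike_reads`, i.e. signal is
#' expressed "per million spike-in reads", which makes samples that
#' received the same amount of spike-in material directly comparable
#' regardless of target-genome sequencing depth. With
#' `input_correction = TRUE`, each IP/RNA sample's factor is additionally
#' multiplied by its paired input's `spike_reads / target_reads` ratio
#' (Orlando-style), which requires an `input_id` column mapping each
#' sample to an input/gDNA sample present in the table.
#'
#' @param summary Data frame with columns `sample_id`, `target_reads`,
#'   `spike_reads` and optionally `role`
#'   (`"ip"`, `"input"`, `"rna"`, `"gdna"`) and `input_id`.
#' @param input_correction Apply the paired-input correction (default
#'   `FALSE`).
#' @return A tibble with columns `sample_id` and `alpha` (one row per
#'   sample; with input correction, only non-input samples are
#'   returned). A warning is raised for any sample whose spike reads
#'   exceed half of its total reads (spike dominance).
#' @examples
#' compute_spike_factor(data.frame(
#'   sample_id = c("unt", "tam"),
#'   target_reads = c(2e6, 2e6), spike_reads = c(1e6, 2e6)
#' ))
#' @export
compute_spike_factor <- function(summary, input_correction = FALSE) {
  stopifnot(is.data.frame(summary))
  need <- c("sample_id", "target_reads", "spike_reads")
  if (!all(need %in% names(summary))) {
    abort(paste0("`summary` must have columns ", paste(need, collapse = ", "), "."))
  }
  if (any(summary$spike_reads <= 0)) {
    abort("Every sample needs `spike_reads` > 0 for calibration.")
  }
  if (any(summary$target_reads < 0)) abort("Read counts must be non-negative.")
  dominant <- summary$spike_reads > 0.5 * (summary$spike_reads + summary$target_reads)
  if (any(dominant)) {
    warn(sprintf(
      "Spike reads exceed 50%% of total reads for: %s",
      paste(summary$sample_id[dominant], collapse = ", ")
    ))
  }
  alpha <- 1e6 / summary$spike_reads
  out <- tibble(sample_id = summary$sample_id, alpha = alpha)
  if (input_correction) {
    if (!"input_id" %in% names(summary)) {
      abort("`input_correction = TRUE` requires an `input_id` column.")
    }
    idx <- match(summary$input_id, summary$sample_id)
    keep <- !is.na(idx)
    if (!any(keep)) abort("No sample has a matching input in the table.")
    corr <- summary$spike_reads[idx] / summary$target_reads[idx]
    out <- out[keep, ]
    out$alpha <- out$alpha * corr[keep]
  }
  out
}

#' Apply a calibration factor to a binned signal track
#'
#' Multiplies every bin value of a fixed-width signal track (bedGraph
#' semantics: 0-based, half-open bins) by the sample's calibration
#' factor and records the factor in the track's metadata.
#'
#' @param track Data frame with columns `chrom`, `start`, `end`, `value`.
#' @param factor A single positive number, or a one-row result of
#'   [compute_spike_factor()].
#' @return The calibrated track tibble, with attribute
#'   `calibration_factor`.
#' @export
calibrate_track <- function(track, factor) {
  if (is.data.frame(factor)) {
    stopifnot(nrow(factor) == 1, "alpha" %in% names(factor))
    factor <- factor$alpha
  }
  check_scalar(factor, "factor", 0, open_lower = TRUE)
  track <- validate_track(track)
  track$value <- track$value * factor
  attr(track, "calibration_factor") <- factor
  track
}

validate_track <- function(track) {
  stopifnot(is.data.frame(track))
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(track))) {
    abort(paste0("A signal track needs columns ", paste(need, collapse = ", "), "."))
  }
  as_tibble(track)
}

#' Mean signal of a track over intervals
#'
#' Quantifies a binned signal track over a set of genomic intervals:
#' each interval (optionally extended by `extend` bp on both sides and
#' clipped at 0) receives the mean of the overlapping bin values
#' weighted by overlap length. Intervals are reported in input order;
#' an interval with no overlapping bins scores 0 and is flagged as
#' uncovered.
#'
#' @param track Data frame with `chrom`, `start`, `end`, `value`
#'   (fixed-width, sorted, non-overlapping bins).
#' @param intervals Data frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param extend Symmetric extension in bp (default 0).
#' @return A tibble: `chrom`, `start`, `end`, `name`, `mean_signal`,
#'   `covered_bp`, `covered` (logical).
#' @examples
#' track <- data.frame(
#'   chrom = "chr1", start = c(0, 200), end = c(200, 400),
#'   value = c(10, 30)
#' )
#' quantify_intervals(track, data.frame(chrom = "chr1", start = 100, end = 300))
#' @export
quantify_intervals <- function(track, intervals, extend = 0) {
  track <- validate_track(track)
  stopifnot(is.data.frame(intervals))
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    abort("`intervals` needs columns chrom, start, end.")
  }
  check_scalar(extend, "extend", 0)
  unknown <- setdiff(unique(intervals$chrom), unique(track$chrom))
  if (length(unknown) > 0) {
    abort(paste0(
      "Intervals on chromosomes absent from the track: ",
      paste(unknown, collapse = ", ")
    ))
  }
  iv <- tibble(
    chrom = intervals$chrom,
    start = pmax(intervals$start - extend, 0),
    end = intervals$end + extend,
    name = if ("name" %in% names(intervals)) {
      intervals$name
    } else {
      sprintf("iv_%d", seq_len(nrow(intervals)))
    }
  )
  if (any(iv$end <= iv$start)) abort("Intervals must satisfy start < end.")

  tr_gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = track$start + 1, end = track$end)
  )
  iv_gr <- GenomicRanges::GRanges(
    iv$chrom,
    IRanges::IRanges(start = iv$start + 1, end = iv$end)
  )
  hits <- GenomicRanges::findOverlaps(iv_gr, tr_gr)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(iv_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(tr_gr)[S4Vectors::subjectHits(hits)]
  ))
  q <- S4Vectors::queryHits(hits)
  wsum <- rowsum(ov * track$value[S4Vectors::subjectHits(hits)], q)
  wlen <- rowsum(ov, q)
  idx <- as.integer(rownames(wsum))

  mean_signal <- rep(0, nrow(iv))
  covered_bp <- rep(0, nrow(iv))
  mean_signal[idx] <- wsum[, 1] / wlen[, 1]
  covered_bp[idx] <- wlen[, 1]

  tibble(
    chrom = iv$chrom, start = iv$start, end = iv$end, name = iv$name,
    mean_signal = mean_signal, covered_bp = covered_bp,
    covered = covered_bp > 0
  )
}

#' Per-interval log2 ratio of two quantifications
#'
#' Computes `log2((a + pseudocount) / (b + pseudocount))` for two
#' interval quantifications over the same interval set in the same
#' order (e.g. tamoxifen-treated vs untreated calibrated signal).
#'
#' @param quant_a,quant_b Numeric vectors, or [quantify_intervals()]
#'   results (the `mean_signal` column is used and interval identity is
#'   checked).
#' @param pseudocount Positive stabilizer added to both sides
#'   (default 1).
#' @return Numeric vector of per-interval log2 ratios.
#' @export
log2_change <- function(quant_a, quant_b, pseudocount = 1) {
  check_scalar(pseudocount, "pseudocount", 0, open_lower = TRUE)
  get_vals <- function(q) if (is.data.frame(q)) q$mean_signal else q
  a <- get_vals(quant_a)
  b <- get_vals(quant_b)
  if (length(a) != length(b)) {
    abort("The two quantifications cover different numbers of intervals.")
  }
  if (is.data.frame(quant_a) && is.data.frame(quant_b) &&
    !identical(quant_a$name, quant_b$name)) {
    abort("Interval sets differ between the two quantifications.")
  }
  log2((a + pseudocount) / (b + pseudocount))
}
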
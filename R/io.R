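# file IO: TSV via readr; BED / bedGraph via rtracklayer, converted to
# the package's 0-based half-open tibble conventions

#' Read and write genomic intervals as BED
#'
#' Thin wrappers over [rtracklayer::import.bed()] /
#' [rtracklayer::export.bed()] that exchange the package's interval
#' tibbles (`chrom`, `start`, `end`, optional `name`, `score`,
#' `strand`; 0-based, half-open).
#'
#' @param path File path.
#' @param intervals Interval data frame to write.
#' @return `read_bed()` returns an interval tibble; `write_bed()`
#'   returns `path` invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  sc <- gr$score
  if (!is.null(sc)) out$score <- sc
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  gr <- as_granges0(intervals)
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  if ("score" %in% names(intervals)) gr$score <- intervals$score
  if ("strand" %in% names(intervals)) {
    GenomicRanges::strand(gr) <- intervals$strand
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write binned signal tracks as bedGraph
#'
#' Exchange signal-track tibbles (`chrom`, `start`, `end`, `value`;
#' 0-based, half-open fixed-width bins) with bedGraph files.
#'
#' @param path File path.
#' @param track Signal-track data frame to write.
#' @return `read_bedgraph()` returns a track tibble; `write_bedgraph()`
#'   returns `path` invisibly.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    value = gr$score
  )
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  track <- validate_track(track)
  gr <- as_granges0(track)
  gr$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a FRAP trace from TSV
#'
#' Reads a tab-separated trace with columns `time`, `roi`, `cell` and
#' optionally `background`, returning a [frap_trace()].
#'
#' @param path File path.
#' @param bleach_index 1-based index of the first post-bleach frame.
#' @return A `frap_trace` tibble.
#' @export
read_frap_trace <- function(path, bleach_index) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (all(c("roi", "cell") %in% names(d))) {
    d <- dplyr::rename(d, roi_intensity = "roi", cell_intensity = "cell")
  }
  frap_trace(d, bleach_index)
}

#' Write a FRAP trace to TSV
#'
#' @param trace A `frap_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_frap_trace <- function(trace, path) {
  readr::write_tsv(
    tibble(
      time = trace$time, roi = trace$roi_intensity,
      cell = trace$cell_intensity, background = trace$background
    ),
    path
  )
  invisible(path)
}
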
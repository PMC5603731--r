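#' Parameter set for a simulated toy genome
#'
#' Settings for [simulate_genome()], which builds a single synthetic
#' chromosome carrying non-methylated islands (NMIs) with graded
#' non-methylated-DNA ("Bio-CAP") intensity and rank-assigned H3K4me3,
#' plus background regions, binned signal tracks, and spike-in read
#' totals. The generator's purpose is to give downstream analyses inputs
#' whose expectations are known in closed form.
#'
#' Under the `"monovalent"` occupancy model the expected reader
#' immunoprecipitation (IP) signal over an NMI is proportional to its
#' Bio-CAP intensity alone; under `"multivalent"` it is
#' `biocap * (1 + multivalence_strength * k4_percentile / 100)`, i.e. an
#' occupancy boost that grows with the island's H3K4me3 percentile
#' (percentile midpoints `(rank - 0.5) / n * 100`). H3K4me3 levels are
#' assigned by rank so percentiles are unambiguous, and are paired with
#' Bio-CAP intensities at random.
#'
#' @param n_nmis Number of NMIs.
#' @param n_background_regions Background (non-island) regions drawn with
#'   low uniform signal.
#' @param chrom_length Chromosome length (bp).
#' @param bin_size Track bin width (bp).
#' @param biocap_intensity_range Length-2 range of NMI Bio-CAP
#'   intensities (unitless), sampled uniformly.
#' @param k4_gradient Multiplier mapping the H3K4me3 percentile midpoint
#'   (0-1) to the H3K4me3 track level.
#' @param occupancy_model `"monovalent"` or `"multivalent"`.
#' @param multivalence_strength Non-negative coupling of IP occupancy to
#'   the H3K4me3 percentile; forced to 0 under the monovalent model.
#' @param reads_per_sample Expected target-genome reads per sample.
#' @param spike_reads_per_sample Expected spike-genome reads per sample.
#' @param seed Integer seed.
#' @return A list of class `genome_sim_params`.
#' @export
genome_sim_params <- function(n_nmis = 500,
                              n_background_regions = 200,
                              chrom_length = 5e6,
                              bin_size = 200,
                              biocap_intensity_range = c(1, 10),
                              k4_gradient = 5,
                              occupancy_model = c("multivalent", "monovalent"),
                              multivalence_strength = 2,
                              reads_per_sample = 1e6,
                              spike_reads_per_sample = 1e5,
                              seed = 1L) {
  occupancy_model <- match.arg(occupancy_model)
  check_count(n_nmis, "n_nmis", min = 1L)
  check_count(n_background_regions, "n_background_regions", min = 0L)
  check_scalar(chrom_length, "chrom_length", 0, open_lower = TRUE)
  check_scalar(bin_size, "bin_size", 0, open_lower = TRUE)
  if (bin_size > chrom_length) abort("`bin_size` must not exceed `chrom_length`.")
  stopifnot(length(biocap_intensity_range) == 2, diff(biocap_intensity_range) >= 0)
  check_scalar(multivalence_strength, "multivalence_strength", 0)
  if (occupancy_model == "monovalent") multivalence_strength <- 0
  check_scalar(reads_per_sample, "reads_per_sample", 0, open_lower = TRUE)
  check_scalar(spike_reads_per_sample, "spike_reads_per_sample", 0, open_lower = TRUE)
  structure(
    list(
      n_nmis = as.integer(n_nmis),
      n_background_regions = as.integer(n_background_regions),
      chrom_length = chrom_length, bin_size = bin_size,
      biocap_intensity_range = biocap_intensity_range,
      k4_gradient = k4_gradient,
      occupancy_model = occupancy_model,
      multivalence_strength = multivalence_strength,
      reads_per_sample = reads_per_sample,
      spike_reads_per_sample = spike_reads_per_sample,
      seed = as.integer(seed)
    ),
    class = "genome_sim_params"
  )
}

#' Simulate a toy genome with NMIs, tracks, and spike-in read totals
#'
#' Generates one synthetic chromosome (`"chrS"`) with sorted,
#' non-overlapping NMI and background intervals (BED semantics: 0-based,
#' half-open), a transcription start site at each NMI midpoint with a
#' random strand, four fixed-width binned signal tracks (`biocap`,
#' `h3k4me3`, `ip`, `input`), and a per-sample read summary including
#' spike-genome totals.
#'
#' Expected IP reads are allocated so NMIs carry 90% of the sample's
#' expected depth (distributed proportionally to the occupancy model's
#' mean) and background bins the remaining 10%; IP, input and spike
#' totals are Poisson draws around their means, making [rpois()] count
#' noise the only stochasticity on the sequencing side.
#'
#' @param params A [genome_sim_params()] object.
#' @return A list of class `genome_sim` with elements:
#' \describe{
#'   \item{nmis}{tibble: `chrom`, `start`, `end`, `name`, `biocap`,
#'     `k4_level`, `k4_percentile`, `expected_ip`.}
#'   \item{background}{tibble of background intervals.}
#'   \item{tss}{tibble: `chrom`, `pos`, `name`, `strand`.}
#'   \item{tracks}{named list of signal-track tibbles
#'     (`chrom`, `start`, `end`, `value`), one per signal.}
#'   \item{read_summary}{tibble: `sample_id`, `role`, `target_reads`,
#'     `spike_reads`.}
#'   \item{params}{the generator parameters.}
#' }
#' @examples
#' g <- simulate_genome(genome_sim_params(n_nmis = 50, chrom_length = 1e6, seed = 3))
#' g$nmis
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "genome_sim_params"))
  p <- params
  set.seed(p$seed)
  chrom <- "chrS"
  n_regions <- p$n_nmis + p$n_background_regions
  n_bins <- floor(p$chrom_length / p$bin_size)
  genome_end <- n_bins * p$bin_size

  # lay regions on a regular grid of slots so they are disjoint and sorted
  slot <- floor(genome_end / n_regions)
  min_w <- max(2 * p$bin_size, floor(slot * 0.2))
  max_w <- max(min_w + p$bin_size, floor(slot * 0.6))
  if (max_w >= slot) abort("Chromosome too short for the requested region count.")
  widths <- round(runif(n_regions, min_w, max_w) / p$bin_size) * p$bin_size
  offsets <- floor(runif(n_regions, 0, slot - widths) / p$bin_size) * p$bin_size
  starts <- (seq_len(n_regions) - 1) * slot + offsets
  starts <- floor(starts / p$bin_size) * p$bin_size
  ends <- pmin(starts + widths, genome_end)

  is_nmi <- sort(sample.int(n_regions, p$n_nmis))
  nmi <- tibble(
    chrom = chrom, start = starts[is_nmi], end = ends[is_nmi],
    name = sprintf("NMI_%04d", seq_len(p$n_nmis))
  )
  bg <- tibble(
    chrom = chrom,
    start = starts[setdiff(seq_len(n_regions), is_nmi)],
    end = ends[setdiff(seq_len(n_regions), is_nmi)],
    name = sprintf("BG_%04d", seq_len(p$n_background_regions))
  )

  # Bio-CAP intensity uniform over its range; H3K4me3 by rank, randomly
  # paired with Bio-CAP so the two features are independent a priori
  nmi$biocap <- runif(p$n_nmis, p$biocap_intensity_range[1], p$biocap_intensity_range[2])
  k4_rank <- sample.int(p$n_nmis)
  nmi$k4_percentile <- (k4_rank - 0.5) / p$n_nmis * 100
  nmi$k4_level <- p$k4_gradient * nmi$k4_percentile / 100

  occ_factor <- 1 + p$multivalence_strength * nmi$k4_percentile / 100
  nmi$expected_ip <- nmi$biocap * occ_factor

  # allocate expected IP depth: 90% over NMIs (prop. to mean occupancy x
  # width), 10% uniform background
  bin_start <- (seq_len(n_bins) - 1) * p$bin_size
  nmi_bin_idx <- purrr::map2(nmi$start, nmi$end, function(s, e) {
    seq(s / p$bin_size + 1, e / p$bin_size)
  })
  nmi_nbins <- lengths(nmi_bin_idx)

  weight <- nmi$expected_ip * nmi_nbins
  ip_rate_nmi <- 0.9 * p$reads_per_sample * nmi$expected_ip / sum(weight)
  bg_rate <- 0.1 * p$reads_per_sample / n_bins

  mean_track <- function(nmi_value_per_bin) {
    v <- rep(0, n_bins)
    for (i in seq_len(p$n_nmis)) v[nmi_bin_idx[[i]]] <- nmi_value_per_bin[i]
    v
  }

  ip_mean <- mean_track(ip_rate_nmi) + bg_rate
  input_mean <- rep(p$reads_per_sample / n_bins, n_bins)
  biocap_track <- mean_track(nmi$biocap)
  k4_track <- mean_track(nmi$k4_level)

  make_track <- function(value) {
    tibble(chrom = chrom, start = bin_start, end = bin_start + p$bin_size, value = value)
  }
  tracks <- list(
    biocap = make_track(biocap_track),
    h3k4me3 = make_track(k4_track),
    ip = make_track(rpois(n_bins, ip_mean)),
    input = make_track(rpois(n_bins, input_mean))
  )

  read_summary <- tibble(
    sample_id = c("ip", "input"),
    role = c("ip", "input"),
    target_reads = c(sum(tracks$ip$value), sum(tracks$input$value)),
    spike_reads = rpois(2, p$spike_reads_per_sample)
  )

  tss <- tibble(
    chrom = chrom,
    pos = floor((nmi$start + nmi$end) / 2),
    name = sub("NMI", "TSS", nmi$name),
    strand = sample(c("+", "-"), p$n_nmis, replace = TRUE)
  )

  structure(
    list(
      nmis = nmi, background = bg, tss = tss, tracks = tracks,
      read_summary = read_summary, params = p
    ),
    class = "genome_sim"
  )
}

#' Simulate paired ChIP conditions with a global signal loss
#'
#' Builds two sequencing samples over the same toy genome — a reference
#' condition and a perturbed condition in which every target-genome
#' signal is scaled by `signal_loss` (e.g. 0.5 for a true genome-wide
#' two-fold loss) — under the spike-in sequencing model: each sample
#' contains a fixed amount of spike-genome material, the library is
#' sequenced to the same total depth, and reads split between target
#' and spike in proportion to the material present. A genuinely global
#' loss therefore leaves naive per-million-target-read normalization
#' blind (both conditions look identical) while the spike fraction
#' shifts, which is exactly what spike calibration recovers.
#'
#' @param genome A [simulate_genome()] result providing the reference
#'   IP mean structure.
#' @param signal_loss Multiplier on all target signal in the perturbed
#'   condition (0, 1\]).
#' @param total_depth Total reads sequenced per sample (target +
#'   spike).
#' @param spike_material Spike material as a fraction of the reference
#'   condition's target material (default 0.1).
#' @param seed Integer seed.
#' @return A list with `tracks` (named list: `ref`, `perturbed` —
#'   Poisson count tracks) and `read_summary` (tibble with
#'   `sample_id`, `role`, `target_reads`, `spike_reads`).
#' @export
simulate_paired_conditions <- function(genome, signal_loss = 0.5,
                                       total_depth = 2e6,
                                       spike_material = 0.1, seed = 1L) {
  stopifnot(inherits(genome, "genome_sim"))
  check_scalar(signal_loss, "signal_loss", 0, 1, open_lower = TRUE)
  check_scalar(spike_material, "spike_material", 0, open_lower = TRUE)
  set.seed(as.integer(seed))
  ref_mean <- genome$tracks$ip$value # reference per-bin expected structure
  share <- ref_mean / sum(ref_mean) # target material distribution

  sample_reads <- function(loss) {
    target_material <- loss
    spike_frac <- spike_material / (target_material + spike_material)
    target_depth <- total_depth * (1 - spike_frac)
    track <- genome$tracks$ip[, c("chrom", "start", "end")]
    track$value <- rpois(length(share), target_depth * share)
    list(
      track = as_tibble(track),
      target = sum(track$value),
      spike = rpois(1, total_depth * spike_frac)
    )
  }
  ref <- sample_reads(1)
  per <- sample_reads(signal_loss)
  list(
    tracks = list(ref = ref$track, perturbed = per$track),
    read_summary = tibble(
      sample_id = c("ref", "perturbed"),
      role = "ip",
      target_reads = c(ref$target, per$target),
      spike_reads = c(ref$spike, per$spike)
    )
  )
}

#' @export
print.genome_sim <- function(x, ...) {
  cat(sprintf(
    "<genome_sim> %d NMIs + %d background regions on %s (%g bp, %g-bp bins), model=%s (strength %g)\n",
    nrow(x$nmis), nrow(x$background), x$nmis$chrom[1],
    x$params$chrom_length, x$params$bin_size,
    x$params$occupancy_model, x$params$multivalence_strength
  ))
  invisible(x)
}
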
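# independent oracles used across the suite

# brute-force all-pairs interval overlap: does interval i of `a` share
# >= 1 bp with any interval of `b`? O(n*m), no sorting assumptions
brute_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom &
      pmax(a$start[i], b$start) < pmin(a$end[i], b$end))
  }, logical(1))
}

# random interval set on a toy chromosome (may contain overlaps)
random_intervals <- function(n, chrom_length = 1e5, max_width = 2000) {
  start <- sample.int(chrom_length - max_width, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE)
  )
}

# analytic half-time of a biexponential recovery, via uniroot (kept
# independent of chromvalence::half_time's bisection)
oracle_half_time <- function(a1, k1, a2, k2) {
  f <- function(t) a1 * (1 - exp(-k1 * t)) + a2 * (1 - exp(-k2 * t)) - (a1 + a2) / 2
  stats::uniroot(f, c(1e-12, 1e6), tol = 1e-12)$root
}

# noiseless normalized recovery curve built directly from parameters
make_normalized <- function(b, a1, k1, a2, k2, t_max = 60, n = 400) {
  t <- seq(0, t_max, length.out = n)
  out <- tibble::tibble(
    time = t, time_post = t,
    recovery = b + a1 * (1 - exp(-k1 * t)) + a2 * (1 - exp(-k2 * t)),
    phase = "post"
  )
  structure(out,
    bleach_index = 1L,
    class = c("normalized_trace", class(out))
  )
}

# enrichment matrix straight from a simulated genome: per-NMI Bio-CAP
# and H3K4me3 from the generator table, IP quantified from the track
nmi_matrix <- function(genome) {
  q <- quantify_intervals(genome$tracks$ip, genome$nmis)
  tibble::tibble(
    biocap = genome$nmis$biocap,
    h3k4me3 = genome$nmis$k4_level,
    ip = q$mean_signal
  )
}
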
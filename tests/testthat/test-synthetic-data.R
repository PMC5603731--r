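test_that("simulated FRAP traces follow the stated noiseless expectations", {
  # fully immobile: post-bleach ROI stays at bleach_depth x pre-bleach mean
  p <- frap_sim_params(
    amplitude_fast = 0, amplitude_slow = 0, noise_sd = 0,
    acquisition_bleach_rate = 0, bleach_depth = 0.25, seed = 1
  )
  tr <- simulate_frap_trace(p)
  bi <- attr(tr, "bleach_index")
  pre_mean <- mean(tr$roi_intensity[seq_len(bi - 1)])
  expect_equal(unique(tr$roi_intensity[bi:nrow(tr)]), 0.25 * pre_mean)

  # single-exponential half-life identity: at t = 1 s with k = ln 2 the
  # recovery sits exactly halfway up
  p2 <- frap_sim_params(
    amplitude_fast = 1, rate_fast = log(2), amplitude_slow = 0,
    noise_sd = 0, acquisition_bleach_rate = 0, bleach_depth = 0.3,
    frame_rate = 1, n_prebleach = 5, n_postbleach = 20, seed = 1
  )
  tr2 <- simulate_frap_trace(p2)
  bi2 <- attr(tr2, "bleach_index")
  at_1s <- tr2$roi_intensity[which(tr2$time == tr2$time[bi2] + 1)]
  expect_equal(at_1s, 0.3 + 0.7 * 0.5)
})

test_that("FRAP trace generation honours the seed contract", {
  p <- frap_sim_params(noise_sd = 0.02, seed = 42)
  expect_identical(simulate_frap_trace(p), simulate_frap_trace(p))
  p2 <- frap_sim_params(noise_sd = 0.02, seed = 43)
  tr_a <- simulate_frap_trace(p)
  tr_b <- simulate_frap_trace(p2)
  expect_false(identical(tr_a$roi_intensity, tr_b$roi_intensity))
  # same underlying noiseless curve: traces differ only in noise
  expect_lt(max(abs(tr_a$roi_intensity - tr_b$roi_intensity)), 8 * 0.02 * sqrt(2))
})

test_that("invalid FRAP generator settings are rejected", {
  expect_error(frap_sim_params(amplitude_fast = 0.8, amplitude_slow = 0.4), "exceed 1")
  expect_error(frap_sim_params(rate_fast = 0), "range")
  expect_error(frap_sim_params(bleach_depth = 0), "range")
  expect_error(frap_sim_params(frame_rate = Inf), "finite")
})

test_that("simulated titrations match the depletion isotherm", {
  p <- titration_sim_params(
    protein_total = 10, ligand_points = c(0, 10, 1e6), kd_true = 10,
    response_free = 2, response_sat = 5, noise_sd = 0, seed = 1
  )
  s <- simulate_titration(p)
  expect_equal(s$response[1], 2) # zero ligand
  expect_equal(s$response[2], 2 + 3 * 0.3819660113, tolerance = 1e-9)
  expect_equal(s$response[3], 5, tolerance = 1e-4) # saturation limit

  expect_error(titration_sim_params(ligand_points = numeric(0)), "non-empty")
  expect_error(titration_sim_params(ligand_points = c(5, 1)), "increasing")
})

test_that("CSP-mode titrations share the Kd across residues", {
  p <- titration_sim_params(
    readout_mode = "nmr_csp", n_residues = 4, kd_true = 20,
    noise_sd = 0, seed = 3
  )
  s <- simulate_titration(p)
  expect_setequal(unique(s$residue), sprintf("R%02d", 1:4))
  # each residue's trace is proportional to the same fraction-bound
  f <- fraction_bound(5, p$ligand_points, 20)
  for (r in unique(s$residue)) {
    y <- s$csp[s$residue == r]
    expect_equal(cor(y, f), 1, tolerance = 1e-12)
  }
})

test_that("generator means are recovered by averaging many replicates", {
  p <- titration_sim_params(kd_true = 10, noise_sd = 0.05, seed = 1)
  noiseless <- simulate_titration(titration_sim_params(kd_true = 10, noise_sd = 0, seed = 1))
  reps <- vapply(seq_len(1000), function(i) {
    simulate_titration(titration_sim_params(kd_true = 10, noise_sd = 0.05, seed = i))$response
  }, numeric(10))
  expect_equal(rowMeans(reps), noiseless$response, tolerance = 0.02)
})

test_that("toy genome intervals satisfy BED contracts and the occupancy model", {
  p <- genome_sim_params(
    n_nmis = 100, n_background_regions = 40, chrom_length = 2e6,
    multivalence_strength = 2, seed = 5
  )
  g <- simulate_genome(p)
  for (iv in list(g$nmis, g$background)) {
    expect_true(all(iv$start < iv$end))
    expect_true(all(iv$start >= 0) && all(iv$end <= 2e6))
    expect_true(all(diff(iv$start) > 0))
  }
  # non-overlap across the union of both sets
  all_iv <- dplyr::arrange(dplyr::bind_rows(g$nmis, g$background), start)
  expect_true(all(utils::head(all_iv$end, -1) <= utils::tail(all_iv$start, -1)))

  # multivalent mean function: top H3K4me3 decile IP/biocap ratio over
  # bottom decile = (1 + 2 * 0.95) / (1 + 2 * 0.05), percentile midpoints
  ratio <- g$nmis$expected_ip / g$nmis$biocap
  top <- mean(ratio[g$nmis$k4_percentile > 90])
  bottom <- mean(ratio[g$nmis$k4_percentile < 10])
  expect_equal(top / bottom, 2.9 / 1.1, tolerance = 1e-9)

  # monovalent model: ratio constant, identical expectations to strength 0
  gm <- simulate_genome(genome_sim_params(
    n_nmis = 100, n_background_regions = 40, chrom_length = 2e6,
    occupancy_model = "monovalent", seed = 5
  ))
  expect_equal(unique(round(gm$nmis$expected_ip / gm$nmis$biocap, 12)), 1)
  g0 <- simulate_genome(genome_sim_params(
    n_nmis = 100, n_background_regions = 40, chrom_length = 2e6,
    occupancy_model = "multivalent", multivalence_strength = 0, seed = 5
  ))
  expect_equal(g0$nmis$expected_ip, gm$nmis$expected_ip)

  expect_error(
    genome_sim_params(bin_size = 5e6, chrom_length = 2e6),
    "bin_size"
  )
})

test_that("toy genome output is byte-stable under a fixed seed", {
  p <- genome_sim_params(n_nmis = 30, chrom_length = 5e5, seed = 11)
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_identical(g1$nmis, g2$nmis)
  expect_identical(g1$tracks, g2$tracks)
  expect_identical(g1$read_summary, g2$read_summary)
})

test_that("IP read counts converge to the generator's mean structure", {
  # law of large numbers over NMIs within one deep sample: observed
  # per-NMI IP signal tracks the expected occupancy
  g <- simulate_genome(genome_sim_params(
    n_nmis = 300, chrom_length = 3e6, reads_per_sample = 5e6, seed = 8
  ))
  q <- quantify_intervals(g$tracks$ip, g$nmis)
  expect_gt(cor(q$mean_signal, g$nmis$expected_ip), 0.99)
})
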
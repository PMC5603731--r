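test_that("overlap_venn reproduces hand-enumerated overlaps", {
  peaks <- tibble::tibble(chrom = "c", start = c(0, 20, 50), end = c(10, 30, 60))
  nmis <- tibble::tibble(chrom = "c", start = c(5, 25), end = c(15, 35))
  v <- overlap_venn(peaks, nmis)
  expect_equal(v$n_overlapping, c(2, 2))
  expect_equal(v$fraction_overlapping, c(2 / 3, 1))
  expect_equal(v$n_overlapping + v$n_only, v$n) # counts conserve

  vi <- overlap_venn(peaks, peaks)
  expect_equal(vi$fraction_overlapping, c(1, 1))
  vd <- overlap_venn(peaks, tibble::tibble(chrom = "c", start = 100, end = 110))
  expect_equal(vd$fraction_overlapping, c(0, 0))
  ve <- overlap_venn(peaks, tibble::tibble(
    chrom = character(), start = numeric(), end = numeric()
  ))
  expect_true(is.na(ve$fraction_overlapping[2])) # undefined, not 0
})

test_that("overlap_venn agrees with the brute-force all-pairs oracle", {
  set.seed(19)
  for (rep in 1:50) {
    a <- random_intervals(sample(5:60, 1))
    b <- random_intervals(sample(5:60, 1))
    v <- overlap_venn(a, b)
    expect_identical(v$n_overlapping[1], sum(brute_overlaps(a, b)))
    expect_identical(v$n_overlapping[2], sum(brute_overlaps(b, a)))
  }
})

test_that("TSS annotation honours the half-open boundary convention", {
  nmis <- tibble::tibble(
    chrom = "c", start = c(0, 0, 20, 40), end = c(10, 10, 30, 50),
    bound = c(TRUE, TRUE, FALSE, FALSE)
  )
  # TSS at 5 inside [0,10); TSS at 10 NOT inside [0,10); one at 25
  tss <- tibble::tibble(chrom = "c", pos = c(5, 10, 25))
  tab <- annotate_tss(nmis[1:2, ], tss[1, , drop = FALSE])
  expect_equal(tab$n_with_tss, 2)
  tab2 <- annotate_tss(
    tibble::tibble(chrom = "c", start = 0, end = 10, bound = TRUE),
    tibble::tibble(chrom = "c", pos = 10)
  )
  expect_equal(tab2$n_with_tss, 0)

  tab3 <- annotate_tss(nmis, tss)
  expect_equal(sum(tab3$n_with_tss), 3)
  expect_equal(tab3$percent_with_tss[tab3$bound], 100)
  expect_equal(tab3$percent_with_tss[!tab3$bound], 50)
})

test_that("metaprofiles reproduce constructed signals and respect strand", {
  bins <- tibble::tibble(
    chrom = "c", start = seq(0, 1990, 10), end = seq(10, 2000, 10), value = 0
  )
  # uniform track -> flat profile
  u <- bins
  u$value <- 4
  mp <- metaprofile(u, tibble::tibble(chrom = "c", pos = 1000), flank = 300, n_bins = 12)
  expect_equal(mp$mean_signal, rep(4, 12))

  # step at the anchor: left half 0, right half 10
  s <- bins
  s$value[s$start >= 1000] <- 10
  mp2 <- metaprofile(s, tibble::tibble(chrom = "c", pos = 1000, strand = "+"),
    flank = 200, n_bins = 10
  )
  expect_equal(mp2$mean_signal, c(rep(0, 5), rep(10, 5)))

  # minus-strand anchor sees the mirrored profile
  mp3 <- metaprofile(s, tibble::tibble(chrom = "c", pos = 1000, strand = "-"),
    flank = 200, n_bins = 10
  )
  expect_equal(mp3$mean_signal, rev(mp2$mean_signal))

  # two opposite-strand anchors over a mirror-symmetric signal
  # contribute identically after orientation
  sym <- bins
  sym$value <- abs(sym$start + 5 - 1000) / 100
  both <- metaprofile(
    sym, tibble::tibble(chrom = "c", pos = c(1000, 1000), strand = c("+", "-")),
    flank = 200, n_bins = 10
  )
  one <- metaprofile(
    sym, tibble::tibble(chrom = "c", pos = 1000, strand = "+"),
    flank = 200, n_bins = 10
  )
  expect_equal(both$mean_signal, one$mean_signal, tolerance = 1e-12)
  # symmetry about the anchor bin
  expect_equal(one$mean_signal, rev(one$mean_signal), tolerance = 1e-12)

  # anchor fully outside coverage is excluded and counted
  far <- metaprofile(
    u, tibble::tibble(chrom = "c", pos = c(1000, 90000)),
    flank = 100, n_bins = 4
  )
  expect_equal(attr(far, "n_excluded"), 1)
  expect_equal(unique(far$n_anchors), 1L)
})

test_that("percentile binning yields equal populations and rank invariance", {
  m <- tibble::tibble(k4 = 1:10)
  b <- percentile_bins(m, "k4", 5)
  expect_equal(as.integer(table(b$bin)), rep(2L, 5))
  expect_equal(b$bin, rep(1:5, each = 2))

  # adding a constant leaves assignments unchanged
  m2 <- tibble::tibble(k4 = m$k4 + 100)
  expect_equal(percentile_bins(m2, "k4", 5)$bin, b$bin)

  # ties broken by stable input order, populations 2/2
  mt <- tibble::tibble(k4 = c(1, 1, 2, 3))
  bt <- percentile_bins(mt, "k4", 2)
  expect_equal(bt$bin, c(1, 1, 2, 2))
  expect_equal(as.integer(table(bt$bin)), c(2L, 2L))

  expect_error(percentile_bins(tibble::tibble(k4 = rep(1, 10)), "k4", 2), "equal")
  # populations differ by at most one for awkward n
  b7 <- percentile_bins(tibble::tibble(k4 = rnorm(23)), "k4", 7)
  expect_lte(diff(range(table(b7$bin))), 1)
})

test_that("the multivalence index separates occupancy models", {
  # exact proportionality -> flat ratio -> index 0
  set.seed(55)
  m <- tibble::tibble(
    biocap = runif(200, 1, 10),
    h3k4me3 = runif(200)
  )
  m$ip <- 3 * m$biocap
  r <- multivalence_index(m, "ip", n_perm = 100)
  expect_equal(r$index, 0, tolerance = 1e-9)
  expect_false(r$multivalent)

  # noiseless multivalent means -> strictly increasing ratio -> index 1
  g <- simulate_genome(genome_sim_params(
    n_nmis = 200, chrom_length = 2e6, multivalence_strength = 2, seed = 6
  ))
  mm <- tibble::tibble(
    biocap = g$nmis$biocap, h3k4me3 = g$nmis$k4_level,
    ip = g$nmis$expected_ip
  )
  set.seed(1)
  rm_ <- multivalence_index(mm, "ip", n_perm = 100)
  expect_equal(rm_$index, 1)
  expect_true(rm_$multivalent)
  # relative enrichments normalized to each signal's max bin mean
  expect_equal(max(rm_$profile$rel_ip), 1)
  expect_equal(max(rm_$profile$rel_biocap), 1)
  expect_true(all(rm_$profile$rel_ip >= 0 & rm_$profile$rel_ip <= 1))

  # permuted signal lands inside the null band in most trials
  set.seed(14)
  inside <- vapply(1:20, function(i) {
    mp <- m
    mp$ip <- sample(mp$ip)
    rr <- multivalence_index(mp, "ip", n_perm = 100)
    !rr$multivalent
  }, logical(1))
  expect_gte(mean(inside), 0.9)

  ref0 <- m
  ref0$biocap[1:50] <- 0
  ref0$ip <- ref0$biocap
  expect_error(
    multivalence_index(dplyr::mutate(ref0, biocap = 0), "ip"),
    "reference|equal"
  )
})

test_that("rank correlation matches hand-ranked values", {
  expect_equal(rank_correlation(1:4, 1:4), 1)
  expect_equal(rank_correlation(1:4, 4:1), -1)
  expect_equal(rank_correlation(1:4, c(1, 3, 2, 4)), 0.8)
  expect_error(rank_correlation(1:4, rep(2, 4)), "constant")
  expect_error(rank_correlation(1:2, 1:2), "3")
})

test_that("differential-expression classification applies the thresholds exactly", {
  tab <- tibble::tibble(
    gene = letters[1:6],
    log2fc = c(-1.0, -0.5, 1.0, log2(1.5), -log2(1.5), NA),
    fdr = c(0.001, 0.001, 0.02, 0.01, 0.01, 0.5)
  )
  cls <- classify_de(tab)
  expect_equal(
    cls$class,
    c("down", "not_significant", "not_significant", "up", "down", "flagged")
  )
  counts <- attr(cls, "counts")
  expect_equal(sum(counts), nrow(tab)) # partition
  # row order invariance of counts
  cls2 <- classify_de(tab[sample(nrow(tab)), ])
  expect_equal(attr(cls2, "counts"), counts)
})

test_that("expression classification uses a strict -2.5 cutoff", {
  expect_equal(
    classify_expression(c(-3, -2.5, 0)),
    c("lowly_expressed", "expressed", "expressed")
  )
})

test_that("group difference tests handle ties, pairing, and exact extremes", {
  # U = 0 configuration: smallest attainable two-sided p for n = 3, 3
  # is 2 * (3! * 3! / 6!) = 0.1 by exact enumeration
  p <- group_difference_test(c(1, 2, 3), c(10, 11, 12), mode = "mann_whitney")
  expect_equal(p, 0.1, tolerance = 1e-9)
  expect_error(
    group_difference_test(c(1, 2, 3), c(1, 2, 3), mode = "wilcoxon_signed_rank"),
    "zero"
  )
  # paired test detects a consistent shift
  a <- c(1.0, 1.2, 0.9, 1.4, 1.1, 1.3)
  expect_lt(
    group_difference_test(a, a + 0.5, mode = "wilcoxon_signed_rank"),
    0.05
  )
})

test_that("island calling thresholds, merges, and filters runs", {
  tr <- tibble::tibble(
    chrom = "c", start = seq(0, 90, 10), end = seq(10, 100, 10),
    value = c(0, 5, 5, 0, 5, 0, 0, 5, 5, 5)
  )
  no_merge <- call_islands(tr, threshold = 1)
  expect_equal(nrow(no_merge), 3)
  merged <- call_islands(tr, threshold = 1, gap_max = 15)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start[1], 10)
  expect_equal(merged$end[1], 50)
  wide_only <- call_islands(tr, threshold = 1, min_width = 25)
  expect_equal(nrow(wide_only), 1)
})
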
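test_that("double normalization reproduces hand-computed recoveries", {
  # roi pre-bleach mean 50, cell constant 100; post frame roi = 25
  d <- tibble::tibble(
    time = 0:3,
    roi_intensity = c(50, 50, 25, 30),
    cell_intensity = 100,
    background = 0
  )
  nt <- normalize_trace(frap_trace(d, bleach_index = 3))
  expect_equal(nt$recovery[3], 0.5)
  expect_equal(mean(nt$recovery[1:2]), 1)
  expect_equal(nt$time_post, c(-2, -1, 0, 1))
})

test_that("normalization cancels shared photobleaching and background shifts", {
  t <- seq(0, 20, by = 0.25)
  decay <- exp(-0.05 * t)
  d <- tibble::tibble(
    time = t, roi_intensity = 80 * decay, cell_intensity = 200 * decay,
    background = 0
  )
  nt <- normalize_trace(frap_trace(d, bleach_index = 10))
  expect_equal(nt$recovery, rep(1, length(t))) # shared factor cancels

  d2 <- d
  d2$roi_intensity <- d2$roi_intensity + 10
  d2$cell_intensity <- d2$cell_intensity + 10
  d2$background <- 10
  nt2 <- normalize_trace(frap_trace(d2, bleach_index = 10))
  expect_equal(nt2$recovery, nt$recovery) # background invariance

  d3 <- d
  d3$cell_intensity[5] <- -1
  expect_error(normalize_trace(frap_trace(d3, bleach_index = 10)), "not positive")
})

test_that("normalization is idempotent on an already-normalized trace", {
  tr <- simulate_frap_trace(frap_sim_params(seed = 4, noise_sd = 0.01))
  nt <- normalize_trace(tr)
  renorm <- normalize_trace(
    tibble::tibble(
      time = nt$time, roi_intensity = nt$recovery, cell_intensity = 1
    ),
    bleach_index = attr(nt, "bleach_index")
  )
  expect_equal(renorm$recovery, nt$recovery, tolerance = 1e-12)
})

test_that("biexponential fits recover noiseless generating parameters", {
  # single-component curve
  nt1 <- make_normalized(b = 0.3, a1 = 0.7, k1 = log(2), a2 = 0, k2 = 1)
  f1 <- fit_biexponential(nt1)
  expect_equal(f1$bleach_depth_fitted, 0.3, tolerance = 1e-6)
  expect_equal(f1$a1 + f1$a2, 0.7, tolerance = 1e-6)
  expect_equal(f1$t_half, 1, tolerance = 1e-5)

  # two well-separated components recovered to <= 1e-4 relative error
  nt2 <- make_normalized(b = 0.2, a1 = 0.48, k1 = 2.0, a2 = 0.32, k2 = 0.2)
  f2 <- fit_biexponential(nt2)
  expect_equal(f2$bleach_depth_fitted, 0.2, tolerance = 1e-4)
  expect_equal(f2$a1, 0.48, tolerance = 1e-4)
  expect_equal(f2$k1, 2.0, tolerance = 1e-4)
  expect_equal(f2$a2, 0.32, tolerance = 1e-4)
  expect_equal(f2$k2, 0.2, tolerance = 1e-4)
  expect_true(f2$k1 >= f2$k2)

  # immobile trace: no mobile amplitude, flagged, no half time
  nt3 <- make_normalized(b = 0.3, a1 = 0, k1 = 1, a2 = 0, k2 = 0.1)
  f3 <- fit_biexponential(nt3)
  expect_true(f3$immobile)
  expect_true(is.na(f3$t_half))
  expect_lt(f3$a1 + f3$a2, 1e-3)
})

test_that("half_time matches an independent root finder and its invariances", {
  expect_equal(half_time(list(a1 = 1, a2 = 0, k1 = 0.6931, k2 = 1)), 1.0,
    tolerance = 1e-4
  )
  cases <- list(
    c(0.6, 2.0, 0.4, 0.2), c(0.3, 5, 0.5, 1), c(0.9, 0.7, 0.05, 0.07)
  )
  for (cs in cases) {
    got <- half_time(list(a1 = cs[1], k1 = cs[2], a2 = cs[3], k2 = cs[4]))
    expect_equal(got, oracle_half_time(cs[1], cs[2], cs[3], cs[4]),
      tolerance = 1e-8
    )
    # amplitude scale invariance
    expect_equal(
      half_time(list(a1 = 3 * cs[1], k1 = cs[2], a2 = 3 * cs[3], k2 = cs[4])),
      got,
      tolerance = 1e-8
    )
  }
  expect_equal(half_time(list(a1 = 0.6, k1 = 2, a2 = 0.4, k2 = 0.2)), 0.688,
    tolerance = 1e-3
  )
  expect_error(half_time(list(a1 = 0, a2 = 0, k1 = 1, k2 = 1)), "amplitude")
})

test_that("half_time decreases monotonically in either rate", {
  base <- list(a1 = 0.5, a2 = 0.3, k1 = 2, k2 = 0.2)
  t0 <- half_time(base)
  for (k1 in c(3, 5, 10)) {
    t1 <- half_time(modifyList(base, list(k1 = k1)))
    expect_lt(t1, t0)
    t0 <- t1
  }
  t0 <- half_time(base)
  for (k2 in c(0.4, 0.8, 1.6)) {
    t1 <- half_time(modifyList(base, list(k2 = k2)))
    expect_lt(t1, t0)
    t0 <- t1
  }
})

test_that("the simulate-normalize-fit chain recovers half times under mild noise", {
  set.seed(101)
  grid <- expand.grid(k_scale = c(0.5, 1, 2), noise = c(0.005, 0.02))
  rel_err <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ks <- grid$k_scale[i]
    p <- frap_sim_params(
      amplitude_fast = 0.5, rate_fast = 2 * ks,
      amplitude_slow = 0.3, rate_slow = 0.3 * ks,
      noise_sd = grid$noise[i], seed = 7000 + i
    )
    truth <- oracle_half_time(0.5, 2 * ks, 0.3, 0.3 * ks)
    fit <- fit_biexponential(normalize_trace(simulate_frap_trace(p)))
    rel_err[i] <- abs(fit$t_half - truth) / truth
  }
  expect_lte(median(rel_err), 0.05)
})

test_that("cohort comparison behaves at the null and under separation", {
  same <- tibble::tibble(
    group = rep(c("wt", "mut"), each = 4),
    t_half = rep(c(1, 1.2, 0.9, 1.1), 2)
  )
  expect_equal(compare_cohorts(same)$p_value, 1)

  set.seed(2)
  sep <- tibble::tibble(
    group = rep(c("a", "b"), each = 4),
    t_half = c(1, 1, 1, 1, 2, 2, 2, 2) + rnorm(8, 0, 1e-3)
  )
  cc <- compare_cohorts(sep)
  expect_lt(cc$p_value, 1e-4)
  expect_equal(cc$summary$median, c(1, 2), tolerance = 1e-2) # factor order a, b

  expect_error(
    compare_cohorts(tibble::tibble(group = c("a", "a", "b", "b"), t_half = 1)),
    "zero variance"
  )
  expect_error(
    compare_cohorts(tibble::tibble(group = c("a", "b", "b"), t_half = c(1, 2, 3))),
    "at least 2"
  )
})

test_that("separated cohorts are detected by the full pipeline", {
  # t_half 1.0 s vs 0.5 s, n = 12 each (reduced n for the unit suite;
  # the power property holds a fortiori at the study's n = 30)
  run_cohort <- function(k_scale, seeds) {
    vapply(seeds, function(s) {
      p <- frap_sim_params(
        amplitude_fast = 0.5, rate_fast = 2 * k_scale,
        amplitude_slow = 0.3, rate_slow = 0.3 * k_scale,
        noise_sd = 0.02, n_postbleach = 400, seed = s
      )
      fit_biexponential(normalize_trace(simulate_frap_trace(p)))$t_half
    }, numeric(1))
  }
  a <- run_cohort(1, 1:12)
  b <- run_cohort(2, 101:112)
  cc <- compare_cohorts(list(slow = a, fast = b))
  expect_lt(cc$p_value, 0.01)
  expect_equal(median(a) / median(b), 2, tolerance = 0.1)
})
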
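test_that("decay curve construction validates its invariants", {
  t <- (1:64 - 0.5) * 12.5 / 64
  expect_s3_class(decay_curve(t, rpois(64, 50)), "decay_curve")
  expect_error(decay_curve(t, rep(-1, 64)), "non-negative")
  expect_error(decay_curve(t, rep(1.5, 64)), "integer")
  expect_silent(decay_curve(t, rep(1.5, 64), expected = TRUE))
  expect_error(decay_curve(c(t[-1], 20), rpois(64, 5)), "uniform")
})

test_that("decay CSV round trip preserves the histogram", {
  d <- gen_tcspc_decay(2.5, 1, 5e4, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_decay(d, path)
  d2 <- read_decay(path)
  expect_equal(d2$counts, d$counts)
  expect_equal(d2$bin_times_ns, d$bin_times_ns, tolerance = 1e-9)
})

test_that("ROI summation matches a brute-force loop and conserves photons", {
  set.seed(11)
  ny <- 6; nx <- 5; nb <- 16
  cube <- array(rpois(ny * nx * nb, 3), dim = c(ny, nx, nb))
  stack <- flim_stack(cube, (1:nb - 0.5) * 12.5 / nb)
  mask <- matrix(runif(ny * nx) > 0.4, ny, nx)
  thr <- 45
  got <- sum_roi_decay(stack, mask, thr)
  # naive triple loop oracle
  expected <- rep(0, nb)
  for (y in 1:ny) for (x in 1:nx) {
    if (mask[y, x] && sum(cube[y, x, ]) > thr)
      for (b in 1:nb) expected[b] <- expected[b] + cube[y, x, b]
  }
  expect_equal(got$counts, expected)
  intensity <- flim_intensity(stack)
  keep <- mask & intensity > thr
  expect_equal(sum(got$counts), sum(intensity[keep]))
})

test_that("ROI summation identity and additivity", {
  nb <- 16
  h <- rpois(nb, 20)
  cube <- array(0L, dim = c(3, 3, nb))
  cube[1, 1, ] <- h
  stack <- flim_stack(cube, (1:nb - 0.5) / nb)
  expect_equal(sum_roi_decay(stack)$counts, h)
  cube[3, 2, ] <- h
  stack2 <- flim_stack(cube, (1:nb - 0.5) / nb)
  expect_equal(sum_roi_decay(stack2)$counts, 2 * h)
  expect_error(sum_roi_decay(stack, intensity_threshold = 1e6), "no pixels")
})

test_that("tail fit recovers a noiseless monoexponential exactly", {
  d <- gen_tcspc_decay(3.05, 1, 1e6, noise = FALSE)
  f <- tail_fit(d)
  expect_true(f$success)
  expect_equal(f$lifetimes_ns[1], 3.05, tolerance = 1e-6)
  expect_lt(f$chi2_reduced, 1e-12)
})

test_that("tail fit recovers Poisson-sampled lifetimes within tolerance", {
  taus <- vapply(1:25, function(s)
    tail_fit(gen_tcspc_decay(2.5, 1, 1e5, seed = s))$lifetimes_ns[1], 0.0)
  expect_true(all(abs(taus / 2.5 - 1) < 0.05))   # each fit within 5%
  expect_lt(abs(mean(taus) / 2.5 - 1), 0.01)     # ensemble within 1%
})

test_that("monoexponential fit of a biexponential brackets the components", {
  d <- gen_tcspc_decay(c(3.05, 1.5), c(0.5, 0.5), 1e6, noise = FALSE)
  f <- tail_fit(d, n_components = 1)
  expect_true(f$success)
  expect_gt(f$lifetimes_ns[1], 1.5)
  expect_lt(f$lifetimes_ns[1], 3.05)
})

test_that("two-component tail fit resolves a well-separated mixture", {
  d <- gen_tcspc_decay(c(3.0, 0.8), c(0.5, 0.5), 1e6, seed = 4)
  f <- tail_fit(d, n_components = 2)
  expect_true(f$success)
  expect_equal(f$lifetimes_ns[1], 3.0, tolerance = 0.1)
  expect_equal(f$lifetimes_ns[2], 0.8, tolerance = 0.1)
})

test_that("tail fit guards its window and photon preconditions", {
  d <- gen_tcspc_decay(2.5, 1, 1e5, seed = 2)
  expect_error(tail_fit(d, fit_window = c(10, 15)), "shorter than 3x")
  expect_error(tail_fit(d, min_total_counts = 1e9), "minimum")
  expect_error(tail_fit(d, fit_window = c(10, 200)), NA)
})

test_that("model selection prefers one component unless clearly improved", {
  mono <- gen_tcspc_decay(2.5, 1, 1e5, seed = 3)
  expect_identical(model_select(mono), 1L)
  biexp <- gen_tcspc_decay(c(3.0, 0.8), c(0.5, 0.5), 1e6, seed = 2)
  expect_identical(model_select(biexp), 2L)
  expect_identical(model_select(biexp, chi2_improvement_threshold = Inf), 1L)
})

test_that("lifetime-ratio efficiency reproduces the published worked values", {
  expect_equal(round(flim_fret_efficiency(2.22, 3.05)), 27)
  expect_equal(round(flim_fret_efficiency(2.23, 3.05)), 27)
  expect_equal(round(flim_fret_efficiency(2.92, 3.05)), 4)
  expect_equal(round(flim_fret_efficiency(2.41, 3.05)), 21)
  expect_equal(round(flim_fret_efficiency(2.81, 3.11)), 10)
  expect_equal(flim_fret_efficiency(3.05, 3.05), 0)
})

test_that("lifetime-ratio efficiency is scale invariant and flags negatives", {
  expect_equal(flim_fret_efficiency(2.2, 3.0),
               flim_fret_efficiency(4.4, 6.0), tolerance = 1e-12)
  expect_message(e <- flim_fret_efficiency(3.2, 3.0), "negative")
  expect_lt(e, 0)
  expect_error(flim_fret_efficiency(-1, 3), "positive")
})

test_that("lifetime maps recover uniform and two-region truth", {
  scn <- maturation_scenario(36, E_true = 0.27, tau_D_ns = 3.0)
  sim <- gen_flim_stack(12, 12, single_cell_spec(0, radius = 4, center = c(6, 6)),
                        scn, per_pixel_budget = 8000, bins = 64, seed = 21)
  m <- lifetime_map(sim$stack, min_photons_per_pixel = 2000)
  vals <- m[!is.na(m)]
  expect_gt(length(vals), 20)
  expect_lt(abs(mean(vals) / 3.0 - 1), 0.03)
  expect_lt(sd(vals) / mean(vals), 0.03)
  # all-dark stack yields an all-absent map
  dark <- flim_stack(array(0L, dim = c(4, 4, 16)), (1:16 - 0.5) / 16)
  expect_true(all(is.na(lifetime_map(dark))))
})

test_that("two-region lifetime maps separate the regions cleanly", {
  scn <- maturation_scenario(36, E_true = 0.2667, tau_D_ns = 3.0)  # tau_DA 2.2
  specs <- list(list(center = c(6, 6), radius = 4, f = 0),
                list(center = c(6, 17), radius = 4, f = 1))
  sim <- gen_flim_stack(12, 23, specs, scn, per_pixel_budget = 8000,
                        bins = 64, seed = 22)
  m <- lifetime_map(sim$stack, min_photons_per_pixel = 2000)
  r1 <- m[sim$labels == 1]; r1 <- r1[!is.na(r1)]
  r2 <- m[sim$labels == 2]; r2 <- r2[!is.na(r2)]
  sep <- abs(mean(r1) - mean(r2)) /
    sqrt(var(r1) / length(r1) + var(r2) / length(r2))
  expect_gt(sep, 5)
})

test_that("photobleach comparison recovers the bleach contrast", {
  scn <- maturation_scenario(136.5, E_true = 0.27)
  pre <- tail_fit(gen_tcspc_decay(
    mixture_decay_params(0.8, scn)$lifetimes_ns,
    mixture_decay_params(0.8, scn)$amplitudes, 5e5, seed = 5))
  post <- tail_fit(gen_tcspc_decay(scn$tau_D_ns, 1, 5e5, seed = 6))
  cmp <- photobleach_compare(pre, post, scn$tau_D_ns)
  expect_lt(cmp$E_post, cmp$E_pre)
  expect_lt(abs(cmp$E_post), 1.5)  # full bleach returns the donor lifetime
  same <- photobleach_compare(pre, pre, scn$tau_D_ns)
  expect_equal(same$delta_E, 0)
})

test_that("framewise lifetimes are stable under pure intensity bleaching", {
  # 20% intensity loss per block at constant lifetime
  blocks <- lapply(0:4, function(b)
    gen_tcspc_decay(3.05, 1, 2e5 * 0.8^b, seed = 30 + b))
  tab <- framewise_lifetimes(blocks)
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$total_counts) < 0))
  expect_lt(max(abs(tab$tau_ns / 3.05 - 1)), 0.02)
  # identical blocks give identical lifetimes; single block gives one row
  same <- framewise_lifetimes(list(blocks[[1]], blocks[[1]]))
  expect_equal(same$tau_ns[1], same$tau_ns[2])
  expect_equal(nrow(framewise_lifetimes(blocks[1])), 1)
})
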
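test_that("generated spectra are unimodal, placed and deterministic", {
  s <- gen_spectrum(517, 15)
  expect_equal(s$wavelength_nm[which.max(s$value)], 517, tolerance = 1)
  sk <- gen_spectrum(593, 20, skew = 3)
  expect_equal(sk$wavelength_nm[which.max(sk$value)], 593, tolerance = 1)
  # symmetric when skew = 0
  peak_i <- which.max(s$value)
  left <- s$value[peak_i - (1:10)]; right <- s$value[peak_i + (1:10)]
  expect_equal(left, right, tolerance = 1e-6)
  expect_equal(spectrum_integral(area_normalize(s)), 1, tolerance = 1e-9)
  expect_identical(gen_spectrum(517, 15, 2)$value,
                   gen_spectrum(517, 15, 2)$value)
})

test_that("emission-scan generator forward model behaves at its edges", {
  pure <- gen_emission_scan(0, donor_ref, acceptor_ref)
  grid <- pure$wavelength_nm
  d <- area_normalize(interpolate_spectrum(donor_ref, grid))$value
  expect_equal(pure$intensity, 1000 * 0.8 * d, tolerance = 1e-12)
  expect_error(gen_emission_scan(1, donor_ref, acceptor_ref), "E_true")
})

test_that("direct acceptor excitation biases the recovered efficiency upward", {
  clean <- gen_emission_scan(0.3, donor_ref, acceptor_ref)
  direct <- gen_emission_scan(0.3, donor_ref, acceptor_ref,
                              direct_excitation_fraction = 0.1)
  e <- function(scan) spectral_fret_efficiency(
    linear_unmix(scan, donor_ref, acceptor_ref), 0.8, 0.54)
  expect_equal(e(clean), 30, tolerance = 1e-9)
  expect_gt(e(direct), 30.5)
})

test_that("expected TCSPC histograms equal the closed-form bin integrals", {
  bins <- 64; range_ns <- 12.5
  d <- gen_tcspc_decay(c(3.0, 1.2), c(0.6, 0.4), 1e5,
                       background_fraction = 0.1, bins = bins,
                       range_ns = range_ns, noise = FALSE)
  edges <- seq(0, range_ns, length.out = bins + 1)
  expected <- sapply(seq_len(bins), function(i) {
    part <- function(tau, a) a * (exp(-edges[i] / tau) -
                                    exp(-edges[i + 1] / tau)) /
      (1 - exp(-range_ns / tau))
    0.9 * (part(3.0, 0.6) + part(1.2, 0.4)) + 0.1 / bins
  })
  expect_equal(d$counts, 1e5 * expected, tolerance = 1e-12)
  expect_equal(sum(d$counts), 1e5, tolerance = 1e-9)
})

test_that("realized photon totals fluctuate around the requested budget", {
  totals <- vapply(1:300, function(s)
    sum(gen_tcspc_decay(2.5, 1, 2e4, bins = 64, seed = s)$counts), 0.0)
  expect_lt(abs(mean(totals) / 2e4 - 1), 0.01)
})

test_that("decay generation is deterministic under a fixed seed", {
  d1 <- gen_tcspc_decay(2.5, 1, 1e4, seed = 5)
  d2 <- gen_tcspc_decay(2.5, 1, 1e4, seed = 5)
  expect_identical(d1$counts, d2$counts)
  expect_error(gen_tcspc_decay(c(2, 3), c(0.7, 0.7), 1e4), "sum to 1")
})

test_that("huge-budget decays round trip through the tail fit", {
  d <- gen_tcspc_decay(3.05, 1, 1e7, seed = 8)
  f <- tail_fit(d)
  expect_lt(abs(f$lifetimes_ns[1] / 3.05 - 1), 0.005)
})

test_that("FLIM stack generator honours geometry and truth", {
  scn <- maturation_scenario(36, E_true = 0.27, tau_D_ns = 3.05)
  sim <- gen_flim_stack(16, 16, single_cell_spec(1, radius = 5),
                        scn, per_pixel_budget = 500, bins = 64, seed = 31)
  expect_s3_class(sim$stack, "flim_stack")
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$E_apparent_percent, 27, tolerance = 0.01)
  # the ROI decay recovers the quenched lifetime
  f <- tail_fit(sum_roi_decay(sim$stack, sim$labels == 1),
                min_total_counts = 500)
  expect_equal(f$lifetimes_ns[1], scn$tau_DA_ns, tolerance = 0.05)
  # overlap and bounds are rejected
  expect_error(gen_flim_stack(16, 16, list(
    list(center = c(8, 8), radius = 5, f = 0),
    list(center = c(10, 10), radius = 5, f = 1)), scn), "overlapping")
  expect_error(gen_flim_stack(8, 8, single_cell_spec(0, center = c(40, 40)),
                              scn), "outside")
  # zero cells: an empty, dark stack
  empty <- gen_flim_stack(6, 6, list(), scn, seed = 1)
  expect_equal(sum(empty$stack$counts), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("two-channel image truth slopes are recovered by the analysis", {
  sim <- gen_two_channel_image(60, 60, grid_cell_specs(9, f = 0.9),
                               E_true = 0.27, seed = 41)
  sub <- background_subtract(sim$image, sim$labels)
  slopes <- image_slopes(sub, sim$labels, min_pixels = 30)
  expect_equal(nrow(slopes), 9)
  expect_lt(abs(stats::median(slopes$slope) - sim$truth$true_slope[1]),
            0.05 * sim$truth$true_slope[1] + 0.01)
  # dark cohort: truth slope 0 and measured slopes cluster at 0
  dark <- gen_two_channel_image(60, 60, grid_cell_specs(9, f = 0),
                                E_true = 0.27, seed = 42)
  expect_true(all(dark$truth$true_slope == 0))
  sub_d <- background_subtract(dark$image, dark$labels)
  slopes_d <- image_slopes(sub_d, dark$labels, min_pixels = 30)
  expect_lt(max(abs(slopes_d$slope)), 0.02)
})

test_that("image generation is deterministic and rejects bad gains", {
  s1 <- gen_two_channel_image(30, 30, grid_cell_specs(1), seed = 3)
  s2 <- gen_two_channel_image(30, 30, grid_cell_specs(1), seed = 3)
  expect_identical(s1$image$green, s2$image$green)
  expect_error(gen_two_channel_image(30, 30, grid_cell_specs(1),
                                     gain_green = 0), "gains")
})

test_that("cohort time series rises from zero efficiency with the days", {
  scn <- maturation_scenario(136.5, E_true = 0.27)
  coh <- gen_cohort_timeseries(c(0, 1, 3, 5), scn, t_half_min = 6200,
                               cells_per_day = 4, per_pixel_budget = 300,
                               bins = 64, seed = 51)
  truth <- attr(coh, "truth")
  by_day <- tapply(truth$E_apparent_percent, truth$day, mean)
  expect_equal(unname(by_day[["0"]]), 0, tolerance = 1e-6)
  expect_true(all(diff(by_day) > 0))
  coh2 <- gen_cohort_timeseries(c(0, 1, 3, 5), scn, t_half_min = 6200,
                                cells_per_day = 4, per_pixel_budget = 300,
                                bins = 64, seed = 51)
  expect_identical(attr(coh2, "truth"), truth)
})
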
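test_that("background subtraction removes a constant offset", {
  set.seed(5)
  g <- matrix(rpois(400, 50), 20, 20)
  r <- matrix(rpois(400, 30), 20, 20)
  img <- two_channel_image(g, r)
  shifted <- two_channel_image(g + 7, r + 7)
  masks <- matrix(0L, 20, 20); masks[5:10, 5:10] <- 1L
  a <- background_subtract(img, masks)
  b <- background_subtract(shifted, masks)
  # shift invariance: adding a constant to both channels changes nothing
  # once the (median) background is re-estimated
  expect_equal(b$green, a$green)
  expect_equal(b$red, a$red)
  # constant image: everything outside the mask defines the background
  const <- two_channel_image(matrix(9, 8, 8), matrix(4, 8, 8))
  sub <- background_subtract(const, matrix(c(1, rep(0, 63)), 8, 8))
  expect_true(all(sub$green == 0) && all(sub$red == 0))
  zero <- two_channel_image(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(background_subtract(zero, matrix(0L, 4, 4))$green,
               matrix(0, 4, 4))
})

test_that("percentile fallback applies when no masks exist", {
  set.seed(6)
  g <- matrix(rpois(400, 10), 20, 20); g[8:12, 8:12] <- 500
  img <- two_channel_image(g, g)
  sub <- background_subtract(img)
  expect_lt(stats::median(sub$green[g < 100]), stats::median(g[g < 100]))
})

test_that("segmentation labels disjoint bright regions deterministically", {
  g <- matrix(0, 40, 40)
  g[5:12, 5:12] <- 100
  g[25:32, 25:32] <- 100
  img <- two_channel_image(g, g * 0)
  lab <- segment_cells(img, threshold = 10, min_area = 20)
  expect_equal(max(lab), 2)
  expect_equal(sort(unique(as.vector(lab))), c(0, 1, 2))
  expect_equal(lab[6, 6], 1L)   # raster-order labelling
  expect_equal(lab[26, 26], 2L)
  empty <- two_channel_image(matrix(0, 10, 10), matrix(0, 10, 10))
  expect_equal(max(segment_cells(empty, threshold = 1)), 0)
})

test_that("segmentation recovers generator cell count", {
  sim <- gen_two_channel_image(60, 60, grid_cell_specs(9), E_true = 0.27,
                               seed = 12)
  sub <- background_subtract(sim$image, sim$labels)
  lab <- segment_cells(sub, threshold = 20, min_area = 30)
  expect_equal(max(lab), 9)
})

test_that("cell slope regression matches exact and degenerate cases", {
  g <- matrix(seq(0, 100, length.out = 64), 8, 8)
  img <- two_channel_image(g, 0.5 * g)
  mask <- matrix(TRUE, 8, 8)
  rec <- cell_intensity_slope(img, mask, min_pixels = 10)
  expect_equal(rec$slope, 0.5, tolerance = 1e-12)
  expect_equal(rec$r_squared, 1, tolerance = 1e-12)
  # dark acceptor: red identically zero gives slope 0
  dark <- two_channel_image(g, g * 0)
  expect_equal(cell_intensity_slope(dark, mask, min_pixels = 10)$slope, 0)
  flat <- two_channel_image(matrix(5, 8, 8), matrix(3, 8, 8))
  expect_error(cell_intensity_slope(flat, mask, min_pixels = 10),
               "zero variance")
  expect_error(cell_intensity_slope(img, mask, min_pixels = 100), "minimum")
})

test_that("noisy slope estimate covers the truth at its own 99% CI", {
  set.seed(8)
  g <- matrix(runif(1000, 0, 200), 40, 25)
  r <- 0.8 * g + rnorm(1000, 0, 10)
  img <- two_channel_image(g, pmax(r, 0))
  rec <- cell_intensity_slope(img, matrix(TRUE, 40, 25))
  fit <- lm(as.vector(img$red) ~ as.vector(img$green))
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(rec$slope - 0.8), qnorm(0.995) * se)
})

test_that("slope scales with red-channel gain", {
  set.seed(9)
  g <- matrix(runif(400, 0, 100), 20, 20)
  r <- 0.4 * g
  s1 <- cell_intensity_slope(two_channel_image(g, r),
                             matrix(TRUE, 20, 20))$slope
  s3 <- cell_intensity_slope(two_channel_image(g, 3 * r),
                             matrix(TRUE, 20, 20))$slope
  expect_equal(s3, 3 * s1, tolerance = 1e-9)
})

test_that("slope histograms bin as documented", {
  one <- data.frame(slope = 0.3)
  h <- slope_histogram(one, bin_width = 0.1)
  expect_equal(sum(h$count), 1)
  expect_equal(sum(h$count > 0), 1)
  h2 <- slope_histogram(data.frame(slope = c(0, 0, 0, 1, 1)), bin_width = 1)
  expect_equal(h2$count[h2$bin_left == 0], 3)
  expect_equal(h2$count[h2$bin_left == 1], 2)
})

test_that("dark- and mature-acceptor cohorts produce distinct histograms", {
  set.seed(14)
  specs_dark <- grid_cell_specs(9, f = 0.02)
  specs_mature <- grid_cell_specs(9, f = 0.95)
  run <- function(specs, seed) {
    sim <- gen_two_channel_image(60, 60, specs, E_true = 0.27, seed = seed)
    sub <- background_subtract(sim$image, sim$labels)
    image_slopes(sub, sim$labels, min_pixels = 30)
  }
  dark <- do.call(rbind, lapply(1:3, function(i) run(specs_dark, 100 + i)))
  mature <- do.call(rbind, lapply(1:3, function(i) run(specs_mature, 200 + i)))
  expect_lt(stats::median(dark$slope), 0.02)
  expect_gt(stats::median(mature$slope), 10 * stats::median(dark$slope))
  # bimodal pooled cohort: the two modes are recovered
  pooled <- rbind(dark, mature)
  h <- slope_histogram(pooled, bin_width = 0.02)
  occupied <- h$bin_mid[h$count > 0]
  expect_lt(min(abs(occupied - stats::median(dark$slope))), 0.03)
  expect_lt(min(abs(occupied - stats::median(mature$slope))), 0.03)
})

test_that("median slope rises with the cohort's mature fraction", {
  meds <- vapply(c(0.1, 0.4, 0.8), function(f) {
    sim <- gen_two_channel_image(60, 60, grid_cell_specs(9, f = f),
                                 E_true = 0.27, seed = round(1000 * f))
    sub <- background_subtract(sim$image, sim$labels)
    stats::median(image_slopes(sub, sim$labels, min_pixels = 30)$slope)
  }, 0.0)
  expect_true(all(diff(meds) > 0))
})
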
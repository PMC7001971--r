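#' Generate a smooth unimodal reference spectrum
#'
#' Produces a skew-normal-shaped curve on a 1 nm grid spanning the peak
#' plus/minus five widths, with the mode placed at `peak_nm` (within the
#' grid resolution). Stands in for purified-protein emission or absorption
#' spectra; real fluorescent-protein spectra are asymmetric, which the skew
#' parameter emulates.
#'
#' @param peak_nm Peak wavelength, nm.
#' @param width_nm Width (scale) parameter, nm (> 0).
#' @param skew Skewness parameter; 0 gives a symmetric Gaussian, positive
#'   values a red tail.
#' @param kind Spectrum kind, as in [spectrum()].
#' @return A [spectrum()] with peak value 1.
#' @export
gen_spectrum <- function(peak_nm, width_nm, skew = 0,
                         kind = c("emission_au", "absorption_extinction")) {
  kind <- match.arg(kind)
  if (width_nm <= 0) stop("width_nm must be positive")
  shape <- function(x, loc) {
    z <- (x - loc) / width_nm
    2 / width_nm * stats::dnorm(z) * stats::pnorm(skew * z)
  }
  # place the distribution mode at peak_nm: locate the mode numerically
  fine <- seq(-4 * width_nm, 4 * width_nm, length.out = 8001)
  mode_off <- fine[which.max(shape(fine, 0))]
  loc <- peak_nm - mode_off
  grid <- seq(floor(peak_nm - 5 * width_nm), ceiling(peak_nm + 5 * width_nm),
              by = 1)
  v <- shape(grid, loc)
  spectrum(grid, v / max(v), kind)
}

#' Simulate a mixed donor + acceptor emission scan
#'
#' Forward model of a sensitized-emission measurement: exciting the donor
#' of a tandem construct with true transfer efficiency `E_true` yields
#' donor emission proportional to `(1 - E_true) * QY_D` and acceptor
#' emission proportional to `E_true * QY_A`, plus an optional directly
#' excited acceptor term (`direct_excitation_fraction * QY_A`) that the
#' unmixing-based efficiency estimate does not correct for and which
#' therefore biases it upward. With `noise_sigma = 0` and no direct
#' excitation, unmixing followed by the efficiency formula recovers
#' `E_true` exactly.
#'
#' @param E_true True FRET efficiency in [0, 1).
#' @param donor_ref,acceptor_ref Reference emission [spectrum()] objects;
#'   area-normalized internally on the scan grid.
#' @param quantum_yield_donor,quantum_yield_acceptor Quantum yields.
#' @param direct_excitation_fraction Fraction of acceptors excited
#'   directly at the donor excitation wavelength (default 0).
#' @param amplitude Overall scan amplitude (photon-scale units).
#' @param noise_sigma Gaussian noise standard deviation, in units of the
#'   scan (0 = noiseless).
#' @param grid_nm Scan wavelength grid (default 490-750 nm, 1 nm steps).
#' @param excitation_nm Donor excitation wavelength (default 470 nm).
#' @param seed Optional seed for the noise draw.
#' @return An [emission_scan()].
#' @export
gen_emission_scan <- function(E_true, donor_ref, acceptor_ref,
                              quantum_yield_donor = 0.8,
                              quantum_yield_acceptor = 0.54,
                              direct_excitation_fraction = 0,
                              amplitude = 1000, noise_sigma = 0,
                              grid_nm = seq(490, 750, by = 1),
                              excitation_nm = 470, seed = NULL) {
  if (E_true < 0 || E_true >= 1) stop("E_true must lie in [0, 1)")
  if (direct_excitation_fraction < 0)
    stop("direct_excitation_fraction must be >= 0")
  fd <- area_normalize(interpolate_spectrum(donor_ref, grid_nm))$value
  fa <- area_normalize(interpolate_spectrum(acceptor_ref, grid_nm))$value
  clean <- amplitude * ((1 - E_true) * quantum_yield_donor * fd +
                          (E_true + direct_excitation_fraction) *
                          quantum_yield_acceptor * fa)
  y <- if (noise_sigma > 0) {
    add_noise <- function() clean + stats::rnorm(length(clean), 0, noise_sigma)
    noisy <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
    pmax(noisy, 0)
  } else clean
  emission_scan(grid_nm, y, excitation_nm)
}

# Expected fraction of photons per bin for a (possibly multi-component)
# exponential decay truncated to one excitation period, plus a uniform
# background floor. Closed-form bin integrals, so the noiseless histogram
# is analytic.
tcspc_bin_probs <- function(lifetimes, amplitudes, bins, range_ns,
                            background_fraction = 0) {
  if (abs(sum(amplitudes) - 1) > 1e-9)
    stop("amplitudes must sum to 1")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must lie in [0, 1)")
  edges <- seq(0, range_ns, length.out = bins + 1)
  p <- rep(0, bins)
  for (i in seq_along(lifetimes)) {
    tau <- lifetimes[i]
    norm <- 1 - exp(-range_ns / tau)
    p <- p + amplitudes[i] *
      (exp(-edges[-(bins + 1)] / tau) - exp(-edges[-1] / tau)) / norm
  }
  (1 - background_fraction) * p + background_fraction / bins
}

#' Simulate a TCSPC photon-count decay histogram
#'
#' Photons are distributed over uniform time bins with expected content
#' proportional to a mixture of exponential decays (truncated to one
#' excitation period) plus a uniform background; bin counts are drawn as
#' independent Poisson variates so the realized total is Poisson around
#' `total_photons`. With `noise = FALSE` the analytic expected histogram
#' is returned instead (real-valued, marked `expected`).
#'
#' @param lifetimes Component lifetimes, ns.
#' @param amplitudes Component amplitudes summing to 1.
#' @param total_photons Expected total photon count (>= 1).
#' @param background_fraction Fraction of photons arriving uniformly in
#'   time (dark counts / room light), in [0, 1).
#' @param bins Number of time bins (default 256).
#' @param range_ns Histogram span, ns (default 12.5 ns, one period of an
#'   80 MHz pulsed laser).
#' @param noise If `FALSE`, return the noiseless expected histogram.
#' @param seed Optional seed.
#' @return A [decay_curve()] with bin-center times.
#' @export
gen_tcspc_decay <- function(lifetimes, amplitudes = rep(1 / length(lifetimes),
                                                        length(lifetimes)),
                            total_photons = 1e5, background_fraction = 0,
                            bins = 256, range_ns = 12.5, noise = TRUE,
                            seed = NULL) {
  if (total_photons < 1) stop("total_photons must be >= 1")
  p <- tcspc_bin_probs(lifetimes, amplitudes, bins, range_ns,
                       background_fraction)
  centers <- (seq_len(bins) - 0.5) * range_ns / bins
  mu <- total_photons * p
  if (!noise)
    return(decay_curve(centers, mu, expected = TRUE))
  draw <- function() stats::rpois(bins, mu)
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  decay_curve(centers, counts)
}

# Elliptical cell footprint helper: logical mask and a smooth radial
# expression profile (1 at the center, ~exp(-2) at the rim).
cell_footprint <- function(ny, nx, center, radius) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  r2 <- ((yy - center[1]) / radius[1])^2 + ((xx - center[2]) / radius[length(radius)])^2
  list(mask = r2 <= 1, profile = exp(-2 * r2))
}

check_cells_fit <- function(ny, nx, specs) {
  occupied <- matrix(FALSE, ny, nx)
  for (s in specs) {
    fp <- cell_footprint(ny, nx, s$center, s$radius)
    if (!any(fp$mask)) stop("cell lies outside the image bounds")
    if (any(fp$mask & occupied)) stop("overlapping cells are not supported")
    occupied <- occupied | fp$mask
  }
  invisible(TRUE)
}

#' Simulate a FLIM stack of cells with partially mature acceptors
#'
#' Builds a photon-count cube in which each cell's pixels draw Poisson
#' photon histograms from the donor decay mixture determined by that
#' cell's mature acceptor fraction `f` (see [mixture_decay_params()]);
#' background pixels are dark. The returned truth table records, per cell,
#' the mixture parameters and the apparent efficiency a noiseless
#' monoexponential tail fit of that mixture would report.
#'
#' @param ny,nx Image dimensions in pixels.
#' @param cell_specs List of cell specifications, each a list with
#'   `center = c(y, x)`, `radius` (scalar or `c(ry, rx)`), `f` (mature
#'   fraction), and optional `brightness` multiplier. Overlapping or
#'   out-of-bounds cells are rejected.
#' @param scenario A [maturation_scenario()] shared by all cells.
#' @param per_pixel_budget Expected photons per cell pixel (before the
#'   brightness multiplier).
#' @param bins,range_ns Histogram geometry.
#' @param seed Optional seed.
#' @return A list with `stack` (a [flim_stack()]), `labels` (integer cell
#'   label matrix) and `truth` (data.frame: `cell_id`, `f`,
#'   `tau_D_ns`, `tau_DA_ns`, `E_apparent_percent`, `n_pixels`).
#' @export
gen_flim_stack <- function(ny, nx, cell_specs, scenario,
                           per_pixel_budget = 200, bins = 256,
                           range_ns = 12.5, seed = NULL) {
  stopifnot(inherits(scenario, "maturation_scenario"))
  check_cells_fit(ny, nx, cell_specs)
  build <- function() {
    cube <- array(0L, dim = c(ny, nx, bins))
    labels <- matrix(0L, ny, nx)
    truth <- vector("list", length(cell_specs))
    for (i in seq_along(cell_specs)) {
      s <- cell_specs[[i]]
      brightness <- if (is.null(s$brightness)) 1 else s$brightness
      fp <- cell_footprint(ny, nx, s$center, s$radius)
      mix <- mixture_decay_params(s$f, scenario)
      p <- tcspc_bin_probs(mix$lifetimes_ns, mix$amplitudes, bins, range_ns)
      npx <- sum(fp$mask)
      mu <- per_pixel_budget * brightness
      draws <- matrix(stats::rpois(npx * bins, rep(mu * p, each = npx)),
                      nrow = npx, ncol = bins)
      flat_idx <- which(fp$mask)
      for (b in seq_len(bins))
        cube[flat_idx + (b - 1L) * ny * nx] <- draws[, b]
      labels[fp$mask] <- i
      truth[[i]] <- data.frame(
        cell_id = i, f = s$f,
        tau_D_ns = scenario$tau_D_ns, tau_DA_ns = scenario$tau_DA_ns,
        E_apparent_percent = apparent_efficiency(s$f, scenario,
                                                 bins = bins,
                                                 range_ns = range_ns),
        n_pixels = npx)
    }
    list(stack = flim_stack(cube, (seq_len(bins) - 0.5) * range_ns / bins),
         labels = labels,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(cell_id = integer(0), f = numeric(0),
                      tau_D_ns = numeric(0), tau_DA_ns = numeric(0),
                      E_apparent_percent = numeric(0), n_pixels = integer(0)))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a two-channel confocal image of tandem-expressing cells
#'
#' Per cell, green-channel intensity is proportional to the donor emission
#' `N * ((1 - f) + f * (1 - E_true)) * QY_D * gain_green` and red-channel
#' intensity to the sensitized (plus directly excited) acceptor emission
#' `N * f * (E_true + direct) * QY_A * gain_red`, where `N` is the cell's
#' expression level, modulated by a smooth radial profile within the cell
#' footprint. Shot noise is Poisson; optional Gaussian read noise and a
#' constant background can be added. The truth table records each cell's
#' expected red-versus-green slope (the ratio of the two rates).
#'
#' @param ny,nx Image dimensions.
#' @param cell_specs List of cells: `center`, `radius`, `expression`
#'   (mean photons per pixel scale `N`), `f`, and optional `E_true`
#'   override.
#' @param E_true Fully mature tandem FRET efficiency (default 0.27).
#' @param quantum_yield_donor,quantum_yield_acceptor Quantum yields.
#' @param gain_green,gain_red Detection gains (> 0).
#' @param direct_excitation_fraction Directly excited acceptor fraction.
#' @param background Constant background level added to both channels.
#' @param read_noise_sd Gaussian read noise SD (0 = none).
#' @param seed Optional seed.
#' @return A list with `image` (a [two_channel_image()]), `labels`, and
#'   `truth` (data.frame: `cell_id`, `f`, `expression`, `true_slope`,
#'   `n_pixels`).
#' @export
gen_two_channel_image <- function(ny, nx, cell_specs, E_true = 0.27,
                                  quantum_yield_donor = 0.8,
                                  quantum_yield_acceptor = 0.54,
                                  gain_green = 1, gain_red = 1,
                                  direct_excitation_fraction = 0,
                                  background = 0, read_noise_sd = 0,
                                  seed = NULL) {
  if (gain_green <= 0 || gain_red <= 0) stop("gains must be positive")
  check_cells_fit(ny, nx, cell_specs)
  build <- function() {
    green_rate <- matrix(background, ny, nx)
    red_rate <- matrix(background, ny, nx)
    labels <- matrix(0L, ny, nx)
    truth <- vector("list", length(cell_specs))
    for (i in seq_along(cell_specs)) {
      s <- cell_specs[[i]]
      e_true <- if (is.null(s$E_true)) E_true else s$E_true
      fp <- cell_footprint(ny, nx, s$center, s$radius)
      g_rate <- s$expression * ((1 - s$f) + s$f * (1 - e_true)) *
        quantum_yield_donor * gain_green
      r_rate <- s$expression * s$f *
        (e_true + direct_excitation_fraction) *
        quantum_yield_acceptor * gain_red
      green_rate[fp$mask] <- green_rate[fp$mask] +
        g_rate * fp$profile[fp$mask]
      red_rate[fp$mask] <- red_rate[fp$mask] + r_rate * fp$profile[fp$mask]
      labels[fp$mask] <- i
      truth[[i]] <- data.frame(cell_id = i, f = s$f,
                               expression = s$expression,
                               true_slope = if (g_rate > 0) r_rate / g_rate
                               else NA_real_,
                               n_pixels = sum(fp$mask))
    }
    g <- matrix(stats::rpois(ny * nx, green_rate), ny, nx)
    r <- matrix(stats::rpois(ny * nx, red_rate), ny, nx)
    if (read_noise_sd > 0) {
      g <- pmax(g + matrix(stats::rnorm(ny * nx, 0, read_noise_sd), ny, nx), 0)
      r <- pmax(r + matrix(stats::rnorm(ny * nx, 0, read_noise_sd), ny, nx), 0)
    }
    list(image = two_channel_image(g, r), labels = labels,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(cell_id = integer(0), f = numeric(0),
                      expression = numeric(0), true_slope = numeric(0),
                      n_pixels = integer(0)))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a multi-day FLIM cohort of a slowly maturing tandem
#'
#' For each requested day post transfection, the kinetic mean mature
#' fraction is `mature_fraction(day * 1440, t_half_min)`; each cell's own
#' fraction is drawn from a Beta distribution centred on that mean
#' (concentration `f_concentration`), capturing cell-to-cell heterogeneity
#' in maturation state. Each day yields one FLIM stack of non-overlapping
#' cells plus the ground-truth table.
#'
#' @param days Numeric vector of days post transfection (>= 0).
#' @param scenario A [maturation_scenario()]; its `t_half_min` drives the
#'   kinetics unless `t_half_min` is given explicitly.
#' @param t_half_min Optional override of the scenario half-time (useful
#'   for modelling in-cell effective maturation slower than the purified
#'   protein value).
#' @param cells_per_day Number of cells per day.
#' @param per_pixel_budget Photons per cell pixel.
#' @param cell_radius Cell radius in pixels.
#' @param f_concentration Beta concentration of the per-cell mature
#'   fraction around the kinetic mean (larger = tighter).
#' @param bins,range_ns Histogram geometry.
#' @param seed Optional seed.
#' @return A list with one element per day, each as returned by
#'   [gen_flim_stack()] plus `day` and `f_mean` entries, and an attached
#'   `truth` data.frame combining all days.
#' @export
gen_cohort_timeseries <- function(days, scenario, t_half_min = NULL,
                                  cells_per_day = 10, per_pixel_budget = 200,
                                  cell_radius = 4, f_concentration = 30,
                                  bins = 128, range_ns = 12.5, seed = NULL) {
  stopifnot(inherits(scenario, "maturation_scenario"))
  if (length(days) == 0) stop("days must be non-empty")
  if (is.null(t_half_min)) t_half_min <- scenario$t_half_min
  build <- function() {
    out <- vector("list", length(days))
    truths <- vector("list", length(days))
    for (di in seq_along(days)) {
      d <- days[di]
      f_mean <- mature_fraction(d * 1440, t_half_min)
      f_cells <- if (f_mean <= 0) rep(0, cells_per_day)
      else if (f_mean >= 1) rep(1, cells_per_day)
      else stats::rbeta(cells_per_day, f_mean * f_concentration,
                        (1 - f_mean) * f_concentration)
      # lay cells on a grid with one-radius margins
      pitch <- 2 * cell_radius + 3
      per_row <- ceiling(sqrt(cells_per_day))
      specs <- lapply(seq_len(cells_per_day), function(i) {
        row <- (i - 1) %/% per_row
        col <- (i - 1) %% per_row
        list(center = c(cell_radius + 2 + row * pitch,
                        cell_radius + 2 + col * pitch),
             radius = cell_radius, f = f_cells[i])
      })
      side_rows <- ceiling(cells_per_day / per_row)
      ny <- cell_radius + 2 + (side_rows - 1) * pitch + cell_radius + 2
      nx <- cell_radius + 2 + (per_row - 1) * pitch + cell_radius + 2
      day_sim <- gen_flim_stack(ny, nx, specs, scenario,
                                per_pixel_budget = per_pixel_budget,
                                bins = bins, range_ns = range_ns)
      day_sim$day <- d
      day_sim$f_mean <- f_mean
      day_sim$truth$day <- d
      out[[di]] <- day_sim
      truths[[di]] <- day_sim$truth
    }
    attr(out, "truth") <- do.call(rbind, truths)
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
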
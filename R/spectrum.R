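#' Construct a fluorophore spectrum
#'
#' A spectrum is a wavelength-indexed curve, either an emission spectrum in
#' arbitrary units (`kind = "emission_au"`) or a molar absorption spectrum
#' (`kind = "absorption_extinction"`, values in M^-1 cm^-1 once scaled to the
#' fluorophore's extinction coefficient; see [scale_to_extinction()]).
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param values Non-negative numeric vector, same length as
#'   `wavelengths_nm`.
#' @param kind One of `"emission_au"` or `"absorption_extinction"`.
#' @return An object of class `fret_spectrum`: a list with elements
#'   `wavelength_nm`, `value` and `kind`.
#' @examples
#' s <- spectrum(c(500, 510, 520), c(0, 1, 0))
#' @export
spectrum <- function(wavelengths_nm, values,
                     kind = c("emission_au", "absorption_extinction")) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have equal length")
  if (length(wavelengths_nm) < 2)
    stop("a spectrum needs at least 2 points")
  if (anyNA(wavelengths_nm) || anyNA(values) ||
      any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("spectrum contains non-finite values")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(values < 0))
    stop("spectrum values must be non-negative")
  structure(list(wavelength_nm = wavelengths_nm, value = values, kind = kind),
            class = "fret_spectrum")
}

#' @export
print.fret_spectrum <- function(x, ...) {
  cat(sprintf("<fret_spectrum> %s, %d points, %.0f-%.0f nm\n",
              x$kind, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects a header `wavelength_nm,value`.
#'
#' @param path Path to a CSV file.
#' @inheritParams spectrum
#' @return A [spectrum()] object.
#' @export
read_spectrum <- function(path, kind = c("emission_au", "absorption_extinction")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum CSV must have columns 'wavelength_nm' and 'value': ", path)
  w <- suppressWarnings(as.numeric(df$wavelength_nm))
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(w) || anyNA(v))
    stop("non-numeric rows in spectrum file: ", path)
  spectrum(w, v, kind)
}

#' Write a spectrum to CSV
#'
#' @param s A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "fret_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelength_nm, value = s$value),
    path, row.names = FALSE)
  invisible(path)
}

#' Trapezoidal integral of a spectrum over its tabulated range
#'
#' @param s A [spectrum()].
#' @return The integral of `value` over wavelength, in value-units times nm.
#' @export
spectrum_integral <- function(s) {
  stopifnot(inherits(s, "fret_spectrum"))
  pracma::trapz(s$wavelength_nm, s$value)
}

#' Area-normalize an emission spectrum
#'
#' Rescales so that the trapezoidal integral over the tabulated wavelength
#' range equals 1 (units nm^-1). Normalization is over the tabulated range
#' only; nothing is extrapolated.
#'
#' @param s An emission [spectrum()].
#' @return The normalized spectrum.
#' @export
area_normalize <- function(s) {
  stopifnot(inherits(s, "fret_spectrum"))
  if (s$kind != "emission_au")
    stop("area_normalize applies to emission spectra")
  a <- spectrum_integral(s)
  if (a <= 0) stop("cannot normalize a spectrum with zero area")
  spectrum(s$wavelength_nm, s$value / a, s$kind)
}

#' Scale an absorption spectrum so its peak equals the extinction coefficient
#'
#' Molar extinction coefficients are defined at the absorption maximum, so a
#' relative absorption curve is converted to M^-1 cm^-1 by setting its peak
#' to the fluorophore's extinction coefficient.
#'
#' @param s An absorption [spectrum()].
#' @param extinction_coefficient_M1cm1 Peak molar extinction, M^-1 cm^-1.
#' @return The scaled spectrum.
#' @export
scale_to_extinction <- function(s, extinction_coefficient_M1cm1) {
  stopifnot(inherits(s, "fret_spectrum"))
  if (extinction_coefficient_M1cm1 <= 0)
    stop("extinction coefficient must be positive")
  pk <- max(s$value)
  if (pk <= 0) stop("cannot scale an all-zero spectrum")
  spectrum(s$wavelength_nm, s$value * (extinction_coefficient_M1cm1 / pk),
           "absorption_extinction")
}

#' Linearly interpolate a spectrum onto a new wavelength grid
#'
#' Wavelengths outside the tabulated range get value 0.
#'
#' @param s A [spectrum()].
#' @param grid_nm Target wavelengths (strictly increasing).
#' @return A [spectrum()] on `grid_nm`.
#' @export
interpolate_spectrum <- function(s, grid_nm) {
  stopifnot(inherits(s, "fret_spectrum"))
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid_nm,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  spectrum(grid_nm, v, s$kind)
}

#' Spectral overlap integral J(lambda)
#'
#' Computes J = integral of fD(lambda) * epsA(lambda) * lambda^4 dlambda,
#' where fD is the area-normalized donor emission spectrum (nm^-1) and epsA
#' the acceptor molar absorption spectrum (M^-1 cm^-1). The two spectra are
#' linearly interpolated onto the union of their wavelength grids restricted
#' to the overlapping range, and integrated by the trapezoid rule. Units of
#' J are M^-1 cm^-1 nm^4.
#'
#' @param donor_em Donor emission [spectrum()]; normalized internally if its
#'   area is not already 1.
#' @param acceptor_abs Acceptor absorption [spectrum()] scaled so its peak
#'   equals the acceptor extinction coefficient (see [scale_to_extinction()]).
#' @return J in M^-1 cm^-1 nm^4. Zero (with a warning) if the wavelength
#'   ranges do not overlap.
#' @export
overlap_integral <- function(donor_em, acceptor_abs) {
  stopifnot(inherits(donor_em, "fret_spectrum"),
            inherits(acceptor_abs, "fret_spectrum"))
  if (donor_em$kind != "emission_au")
    stop("donor_em must be an emission spectrum")
  if (abs(spectrum_integral(donor_em) - 1) > 1e-9)
    donor_em <- area_normalize(donor_em)
  lo <- max(min(donor_em$wavelength_nm), min(acceptor_abs$wavelength_nm))
  hi <- min(max(donor_em$wavelength_nm), max(acceptor_abs$wavelength_nm))
  if (lo >= hi) {
    warning("donor emission and acceptor absorption do not overlap; J = 0")
    return(0)
  }
  grid <- sort(unique(c(donor_em$wavelength_nm, acceptor_abs$wavelength_nm,
                        lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- interpolate_spectrum(donor_em, grid)$value
  ea <- interpolate_spectrum(acceptor_abs, grid)$value
  pracma::trapz(grid, fd * ea * grid^4)
}

#' Förster calculation context
#'
#' Holds the dipole orientation factor kappa^2 and medium refractive index
#' used by [forster_radius()]. Defaults are the standard assumptions for
#' freely rotating fluorophores in aqueous medium: kappa^2 = 0.6667 (2/3 to
#' four figures) and n = 1.33.
#'
#' @param kappa_squared Orientation factor, in [0, 4].
#' @param refractive_index Medium refractive index, >= 1.
#' @return A list of class `forster_context`.
#' @export
forster_context <- function(kappa_squared = 0.6667, refractive_index = 1.33) {
  if (kappa_squared < 0 || kappa_squared > 4)
    stop("kappa_squared must lie in [0, 4]")
  if (refractive_index < 1)
    stop("refractive_index must be >= 1")
  structure(list(kappa_squared = kappa_squared,
                 refractive_index = refractive_index),
            class = "forster_context")
}

#' Förster radius from overlap integral and donor quantum yield
#'
#' R0^6 (in Angstrom^6) = 8.79e-5 * kappa^2 * n^-4 * QY_D * J, with J in
#' M^-1 cm^-1 nm^4. R0 is the donor-acceptor separation at which transfer
#' efficiency is 50%.
#'
#' @param J Overlap integral, M^-1 cm^-1 nm^4 (see [overlap_integral()]).
#' @param quantum_yield_donor Donor fluorescence quantum yield, in (0, 1].
#' @param ctx A [forster_context()].
#' @return Förster radius in Angstrom.
#' @examples
#' forster_radius(4.65e15, 0.8)  # ~64 Angstrom
#' @export
forster_radius <- function(J, quantum_yield_donor, ctx = forster_context()) {
  if (J < 0) stop("overlap integral must be non-negative")
  if (quantum_yield_donor <= 0 || quantum_yield_donor > 1)
    stop("quantum_yield_donor must lie in (0, 1]")
  stopifnot(inherits(ctx, "forster_context"))
  (8.79e-5 * ctx$kappa_squared * ctx$refractive_index^-4 *
     quantum_yield_donor * J)^(1 / 6)
}

#' Photophysical constants of the fluorescent proteins in this toolkit
#'
#' Published constants for the green donors mNeonGreen and mClover3 and the
#' red acceptors mRuby3, mScarlet-I, mCherry and mScarlet: excitation and
#' emission maxima, extinction coefficient (EC), quantum yield (QY), pKa,
#' chromophore maturation half-time, and, for the acceptors, the spectral
#' overlap integral J and Förster radius R0 computed with mNeonGreen as the
#' donor (kappa^2 = 0.6667, n = 1.33).
#'
#' @return A data.frame with one row per fluorophore and columns `name`,
#'   `role`, `lambda_ex_max_nm`, `lambda_em_max_nm`,
#'   `extinction_coefficient_M1cm1`, `quantum_yield`, `pKa`,
#'   `maturation_half_time_min`, `J_M1cm1nm4`, `R0_angstrom` (the last two
#'   are `NA` for donors).
#' @export
fluorophores <- function() {
  data.frame(
    name = c("mNeonGreen", "mClover3",
             "mRuby3", "mScarlet-I", "mCherry", "mScarlet"),
    role = c("donor", "donor", "acceptor", "acceptor", "acceptor", "acceptor"),
    lambda_ex_max_nm = c(506, 506, 558, 569, 587, 569),
    lambda_em_max_nm = c(517, 518, 592, 593, 610, 594),
    extinction_coefficient_M1cm1 = c(116000, 109000, 128000, 104000,
                                     72000, 100000),
    quantum_yield = c(0.80, 0.78, 0.45, 0.54, 0.22, 0.70),
    pKa = c(5.7, 6.5, 4.8, 5.4, 4.5, 5.3),
    maturation_half_time_min = c(10, 43.5, 136.5, 36, 15, 174),
    J_M1cm1nm4 = c(NA, NA, 4.65e15, 3.60e15, 2.28e15, 3.51e15),
    R0_angstrom = c(NA, NA, 64, 61, 57, 61),
    stringsAsFactors = FALSE
  )
}

#' Look up one fluorophore record by name
#'
#' @param name Fluorophore name as listed in [fluorophores()], e.g.
#'   `"mNeonGreen"`.
#' @return A one-row data.frame.
#' @export
fluorophore <- function(name) {
  tab <- fluorophores()
  hit <- tab[tab$name == name, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("unknown fluorophore: ", name,
         " (known: ", paste(tab$name, collapse = ", "), ")")
  hit
}
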
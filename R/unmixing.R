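#' Construct an emission scan
#'
#' An emission scan is the emission intensity of a mixed sample recorded
#' across wavelengths at a fixed donor excitation wavelength (for the
#' green/red pairs in this toolkit, typically 490-750 nm at 470 nm
#' excitation).
#'
#' @param wavelengths_nm Strictly increasing wavelengths, nm.
#' @param intensities Non-negative intensities, arbitrary units.
#' @param excitation_nm Excitation wavelength; must fall below the first
#'   emission wavelength.
#' @return An object of class `emission_scan`.
#' @export
emission_scan <- function(wavelengths_nm, intensities, excitation_nm = 470) {
  s <- spectrum(wavelengths_nm, intensities, "emission_au")
  if (excitation_nm >= wavelengths_nm[1])
    stop("excitation wavelength must be below the first emission wavelength")
  structure(list(wavelength_nm = s$wavelength_nm, intensity = s$value,
                 excitation_nm = excitation_nm),
            class = "emission_scan")
}

#' @export
print.emission_scan <- function(x, ...) {
  cat(sprintf("<emission_scan> %d points, %.0f-%.0f nm, excited at %.0f nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$excitation_nm))
  invisible(x)
}

# Solve min ||y - X b - c|| with b >= 0 (c optional free baseline) by exact
# active-set enumeration: with only two sign-constrained coefficients the
# candidate active sets can be enumerated and the best feasible fit kept.
nnls_two_component <- function(y, donor, acceptor, fit_baseline = FALSE) {
  fit_subset <- function(use_d, use_a) {
    X <- cbind(if (use_d) donor, if (use_a) acceptor,
               if (fit_baseline) rep(1, length(y)))
    if (is.null(X)) {
      coefs <- numeric(0)
      resid <- y
    } else {
      f <- stats::lm.fit(X, y)
      coefs <- f$coefficients
      coefs[is.na(coefs)] <- 0
      resid <- y - X %*% coefs
    }
    i <- 1
    w_d <- 0; w_a <- 0; base <- 0
    if (use_d) { w_d <- coefs[i]; i <- i + 1 }
    if (use_a) { w_a <- coefs[i]; i <- i + 1 }
    if (fit_baseline) base <- coefs[i]
    list(w_d = unname(w_d), w_a = unname(w_a), baseline = unname(base),
         rss = sum(resid^2), feasible = w_d >= 0 && w_a >= 0)
  }
  cands <- list(fit_subset(TRUE, TRUE), fit_subset(TRUE, FALSE),
                fit_subset(FALSE, TRUE), fit_subset(FALSE, FALSE))
  feas <- Filter(function(f) f$feasible, cands)
  feas[[which.min(vapply(feas, `[[`, 0, "rss"))]]
}

#' Linear unmixing of a mixed emission scan
#'
#' Decomposes a measured emission scan into non-negative multiples of a
#' donor-only and an acceptor-only reference spectrum (plus an optional
#' constant baseline), by least squares. The references are interpolated
#' onto the scan's wavelength grid and area-normalized on that grid before
#' fitting, so the recovered weights are comparable across scans.
#'
#' @param scan An [emission_scan()].
#' @param donor_ref,acceptor_ref Reference emission [spectrum()] objects.
#' @param fit_baseline If `TRUE`, also fit a free constant offset
#'   (background term). Default `FALSE`.
#' @param shift_nm Optional wavelength shift (nm) applied to the acceptor
#'   reference before interpolation (positive shifts move it to longer
#'   wavelengths). Accommodates in-cell spectral shifts relative to
#'   purified-protein references.
#' @param condition_limit Reject reference pairs whose design matrix
#'   condition number exceeds this (near-collinear references make the
#'   weights meaningless).
#' @return A list of class `unmix_result` with elements `w_donor`,
#'   `w_acceptor`, `baseline`, `fitted` (reconstructed scan on the scan
#'   grid), `rss` and `r_squared`.
#' @export
linear_unmix <- function(scan, donor_ref, acceptor_ref, fit_baseline = FALSE,
                         shift_nm = 0, condition_limit = 1e8) {
  stopifnot(inherits(scan, "emission_scan"))
  grid <- scan$wavelength_nm
  if (shift_nm != 0)
    acceptor_ref <- spectrum(acceptor_ref$wavelength_nm + shift_nm,
                             acceptor_ref$value, acceptor_ref$kind)
  d <- area_normalize(interpolate_spectrum(donor_ref, grid))$value
  a <- area_normalize(interpolate_spectrum(acceptor_ref, grid))$value
  kond <- kappa(cbind(d, a), exact = TRUE)
  if (!is.finite(kond) || kond > condition_limit)
    stop(sprintf(paste0("donor and acceptor references are collinear on the",
                        " scan grid (condition number %.3g)"), kond))
  y <- scan$intensity
  sol <- nnls_two_component(y, d, a, fit_baseline)
  fitted <- sol$w_d * d + sol$w_a * a + sol$baseline
  tss <- sum((y - mean(y))^2)
  structure(list(w_donor = sol$w_d, w_acceptor = sol$w_a,
                 baseline = sol$baseline, fitted = fitted, rss = sol$rss,
                 r_squared = if (tss > 0) 1 - sol$rss / tss else NA_real_),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> W_D = %.4g, W_A = %.4g, r^2 = %.4f\n",
              x$w_donor, x$w_acceptor, x$r_squared))
  invisible(x)
}

#' FRET efficiency from unmixed component weights
#'
#' Converts the donor and acceptor component weights of an unmixed emission
#' scan to a FRET efficiency, correcting for the quantum-yield difference
#' between the two fluorophores. The default (`variant = "sensitized"`)
#' computes
#' \deqn{E = 100 \cdot \frac{W_A}{W_A + W_D \, QY_A / QY_D}}
#' which equals the fraction of donor excitations transferred when the
#' acceptor component arises purely from sensitized emission. The
#' `"literal"` variant, \eqn{E = 100 \cdot W_A (QY_A/QY_D) / (W_D + W_A)},
#' is provided for comparison with alternative readings of the same
#' weight-ratio formula.
#'
#' @param result An `unmix_result` from [linear_unmix()], or a list with
#'   elements `w_donor` and `w_acceptor`.
#' @param quantum_yield_donor,quantum_yield_acceptor Quantum yields in
#'   (0, 1].
#' @param variant `"sensitized"` (default) or `"literal"`.
#' @return FRET efficiency in percent (0-100 for the default variant).
#' @export
spectral_fret_efficiency <- function(result, quantum_yield_donor,
                                     quantum_yield_acceptor,
                                     variant = c("sensitized", "literal")) {
  variant <- match.arg(variant)
  w_d <- result$w_donor
  w_a <- result$w_acceptor
  if (w_d < 0 || w_a < 0) stop("component weights must be non-negative")
  if (w_d + w_a <= 0) stop("both component weights are zero")
  for (qy in c(quantum_yield_donor, quantum_yield_acceptor))
    if (qy <= 0 || qy > 1) stop("quantum yields must lie in (0, 1]")
  q <- quantum_yield_acceptor / quantum_yield_donor
  if (variant == "sensitized") 100 * w_a / (w_a + w_d * q)
  else 100 * w_a * q / (w_d + w_a)
}
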
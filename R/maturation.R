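#' Maturation scenario for a tandem donor-acceptor construct
#'
#' Bundles the kinetic and photophysical parameters of a donor/acceptor
#' tandem whose acceptor chromophore matures slowly: the acceptor's
#' maturation half-time, the FRET efficiency of the fully mature tandem,
#' and the donor-only lifetime. The quenched donor lifetime is derived as
#' `tau_DA = tau_D * (1 - E_true)`.
#'
#' @param t_half_min Acceptor maturation half-time, minutes.
#' @param E_true FRET efficiency of the fully mature tandem, in [0, 1).
#' @param tau_D_ns Donor-only lifetime, ns (default 3.05, the measured
#'   mNeonGreen donor-only value).
#' @param name Optional scenario label. Passing an acceptor name from
#'   [fluorophores()] (e.g. `"mRuby3"`) fills `t_half_min` from the
#'   published table when it is not supplied.
#' @return A list of class `maturation_scenario`.
#' @export
maturation_scenario <- function(t_half_min = NULL, E_true = 0.27,
                                tau_D_ns = 3.05, name = NULL) {
  if (!is.null(name) && is.null(t_half_min))
    t_half_min <- fluorophore(name)$maturation_half_time_min
  if (is.null(t_half_min)) stop("t_half_min (or a known acceptor name) required")
  if (t_half_min <= 0) stop("t_half_min must be positive")
  if (E_true < 0 || E_true >= 1) stop("E_true must lie in [0, 1)")
  if (tau_D_ns <= 0) stop("tau_D_ns must be positive")
  structure(list(t_half_min = t_half_min, E_true = E_true,
                 tau_D_ns = tau_D_ns,
                 tau_DA_ns = tau_D_ns * (1 - E_true),
                 name = if (is.null(name)) NA_character_ else name),
            class = "maturation_scenario")
}

#' @export
print.maturation_scenario <- function(x, ...) {
  cat(sprintf(paste0("<maturation_scenario>%s t_half = %.1f min, E_true = ",
                     "%.2f, tau_D = %.2f ns, tau_DA = %.2f ns\n"),
              if (is.na(x$name)) "" else paste0(" ", x$name, ":"),
              x$t_half_min, x$E_true, x$tau_D_ns, x$tau_DA_ns))
  invisible(x)
}

#' Mature acceptor fraction after a given expression time
#'
#' First-order chromophore maturation kinetics parameterized by the
#' half-time: f(t) = 1 - 2^(-t / t_half). f(0) = 0, f(t_half) = 0.5, and
#' f increases monotonically towards 1.
#'
#' @param t_min Time since the protein was produced, minutes (>= 0).
#' @param t_half_min Maturation half-time, minutes.
#' @return Mature fraction in [0, 1].
#' @export
mature_fraction <- function(t_min, t_half_min) {
  if (any(t_min < 0)) stop("time must be non-negative")
  if (t_half_min <= 0) stop("t_half_min must be positive")
  1 - 2^(-t_min / t_half_min)
}

#' Donor decay mixture for a partially mature acceptor population
#'
#' With a fraction `f` of acceptors mature, each tandem molecule carries
#' one donor that is either quenched (lifetime tau_DA, weight f) or
#' unquenched (tau_D, weight 1 - f); amplitudes are molecule-weighted. The
#' mixture degenerates to a single component at f = 0 or f = 1.
#'
#' @param f Mature acceptor fraction in [0, 1].
#' @param scenario A [maturation_scenario()].
#' @return A list with `lifetimes_ns = c(tau_D, tau_DA)` and
#'   `amplitudes = c(1 - f, f)` (components with zero amplitude dropped).
#' @export
mixture_decay_params <- function(f, scenario) {
  stopifnot(inherits(scenario, "maturation_scenario"))
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  lifetimes <- c(scenario$tau_D_ns, scenario$tau_DA_ns)
  amplitudes <- c(1 - f, f)
  keep <- amplitudes > 0
  list(lifetimes_ns = lifetimes[keep], amplitudes = amplitudes[keep])
}

#' Apparent FRET efficiency of a partially mature tandem
#'
#' Evaluates the donor decay of the dark/mature mixture, fits it with a
#' single-exponential tail fit (the standard analysis applied to cell
#' data), and converts the fitted lifetime to an efficiency against the
#' scenario's donor-only lifetime. With `photons = NULL` the mixture decay
#' is evaluated noiselessly; otherwise a Poisson photon histogram of that
#' size is simulated first.
#'
#' @param f Mature acceptor fraction in [0, 1].
#' @param scenario A [maturation_scenario()].
#' @param photons Photon budget for a stochastic evaluation, or `NULL`
#'   (default) for the noiseless expected histogram.
#' @param bins,range_ns Histogram geometry (defaults 256 bins over 12.5 ns,
#'   one 80 MHz excitation period).
#' @param seed Random seed for the stochastic evaluation.
#' @return Apparent efficiency in percent. By construction the apparent
#'   value never exceeds the fully mature efficiency: dark acceptors only
#'   dilute the lifetime signal.
#' @export
apparent_efficiency <- function(f, scenario, photons = NULL, bins = 256,
                                range_ns = 12.5, seed = NULL) {
  stopifnot(inherits(scenario, "maturation_scenario"))
  mix <- mixture_decay_params(f, scenario)
  if (is.null(photons)) {
    decay <- gen_tcspc_decay(mix$lifetimes_ns, mix$amplitudes,
                             total_photons = 1e6, bins = bins,
                             range_ns = range_ns, noise = FALSE)
  } else {
    decay <- gen_tcspc_decay(mix$lifetimes_ns, mix$amplitudes,
                             total_photons = photons, bins = bins,
                             range_ns = range_ns, seed = seed)
  }
  fit <- tail_fit(decay, n_components = 1)
  if (!fit$success) stop("tail fit failed: ", fit$message)
  flim_fret_efficiency(fit$lifetimes_ns[1], scenario$tau_D_ns)
}

#' Maturation time-course of apparent FRET efficiency
#'
#' Composes [mature_fraction()] with [apparent_efficiency()] over a set of
#' expression times, producing the model's efficiency-versus-time curve
#' (e.g. across days post transfection).
#'
#' @param times_min Expression times in minutes.
#' @param scenario A [maturation_scenario()].
#' @param ... Passed to [apparent_efficiency()].
#' @return A data.frame with columns `t_min`, `mature_fraction`,
#'   `E_apparent_percent`.
#' @export
maturation_timecourse <- function(times_min, scenario, ...) {
  f <- mature_fraction(times_min, scenario$t_half_min)
  e <- vapply(f, apparent_efficiency, 0.0, scenario = scenario, ...)
  data.frame(t_min = times_min, mature_fraction = f,
             E_apparent_percent = e)
}
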
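#' Construct a TCSPC decay curve
#'
#' A time-correlated single-photon-counting histogram: photon counts in
#' uniform time bins following the excitation pulse.
#'
#' @param bin_times_ns Increasing, uniformly spaced bin-center times, ns.
#' @param counts Non-negative photon counts per bin. Measured histograms
#'   carry integer counts; set `expected = TRUE` for noiseless model-derived
#'   curves with real-valued expected counts.
#' @param n_frames Number of acquisition frames summed into the histogram.
#' @param expected Whether `counts` are real-valued model expectations
#'   rather than measured integer counts.
#' @param meta Optional named list of acquisition metadata (e.g.
#'   `laser_power_W_cm2`).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(bin_times_ns, counts, n_frames = 1L,
                        expected = FALSE, meta = list()) {
  bin_times_ns <- as.numeric(bin_times_ns)
  counts <- as.numeric(counts)
  if (length(bin_times_ns) != length(counts))
    stop("bin_times_ns and counts must have equal length")
  if (length(bin_times_ns) < 4)
    stop("decay curve needs at least 4 bins")
  dt <- diff(bin_times_ns)
  if (any(dt <= 0)) stop("bin times must be increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop("bin times must be uniformly spaced (within 1e-9 ns)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!expected && any(abs(counts - round(counts)) > 1e-9))
    stop("measured counts must be integer-valued; ",
         "use expected = TRUE for model-derived curves")
  structure(list(bin_times_ns = bin_times_ns, counts = counts,
                 n_frames = as.integer(n_frames), expected = expected,
                 meta = meta),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d bins, %.3f-%.3f ns, %s photons\n",
              length(x$counts), min(x$bin_times_ns), max(x$bin_times_ns),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read a decay curve from a CSV file with columns `time_ns,counts`
#'
#' @param path CSV path.
#' @param ... Passed to [decay_curve()].
#' @return A [decay_curve()].
#' @export
read_decay <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ns", "counts") %in% names(df)))
    stop("decay CSV must have columns 'time_ns' and 'counts': ", path)
  decay_curve(df$time_ns, df$counts, ...)
}

#' Write a decay curve to CSV (`time_ns,counts`)
#'
#' @param decay A [decay_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "decay_curve"))
  utils::write.csv(data.frame(time_ns = decay$bin_times_ns,
                              counts = decay$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Construct a FLIM photon-count stack
#'
#' A per-pixel TCSPC acquisition: a photon-count cube indexed (y, x, time
#' bin) plus the shared bin-center times.
#'
#' @param counts 3-D non-negative integer array, dimensions
#'   `c(ny, nx, n_bins)`.
#' @param bin_times_ns Uniform bin-center times, length `n_bins`.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, bin_times_ns) {
  if (length(dim(counts)) != 3)
    stop("counts must be a 3-D array (y, x, time_bin)")
  if (dim(counts)[3] != length(bin_times_ns))
    stop("third dimension of counts must match length of bin_times_ns")
  if (any(counts < 0)) stop("counts must be non-negative")
  dt <- diff(bin_times_ns)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-9)
    stop("bin times must be increasing and uniform")
  structure(list(counts = counts, bin_times_ns = as.numeric(bin_times_ns)),
            class = "flim_stack")
}

#' Total-intensity image of a FLIM stack (per-pixel photon sum)
#'
#' @param stack A [flim_stack()].
#' @return A `ny x nx` matrix of per-pixel total counts.
#' @export
flim_intensity <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  rowSums(stack$counts, dims = 2)
}

#' Sum a region of interest of a FLIM stack into one decay curve
#'
#' Adds the per-pixel histograms of every masked pixel whose total photon
#' count exceeds `intensity_threshold`, producing a single cell-level decay
#' curve. Photons are conserved: the output total equals the sum of the
#' qualifying pixels' totals.
#'
#' @param stack A [flim_stack()].
#' @param roi_mask Logical `ny x nx` matrix selecting the region; default
#'   the whole frame.
#' @param intensity_threshold Minimum per-pixel total count (exclusive) for
#'   a pixel to contribute.
#' @return A [decay_curve()].
#' @export
sum_roi_decay <- function(stack, roi_mask = NULL, intensity_threshold = 0) {
  stopifnot(inherits(stack, "flim_stack"))
  dims <- dim(stack$counts)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(roi_mask), dims[1:2]))
    stop("roi_mask shape must match the stack frame")
  if (intensity_threshold < 0) stop("intensity_threshold must be >= 0")
  keep <- roi_mask & (flim_intensity(stack) > intensity_threshold)
  if (!any(keep)) stop("no pixels remain after masking and thresholding")
  flat <- matrix(stack$counts, nrow = dims[1] * dims[2], ncol = dims[3])
  decay_curve(stack$bin_times_ns, colSums(flat[as.vector(keep), , drop = FALSE]))
}

# Initial parameter guesses for an n-component exponential tail fit:
# offset from the last 5% of bins, lifetimes from log-linear regression of
# the offset-subtracted window (split for two components).
tail_fit_start <- function(t, y, n_components) {
  n <- length(y)
  n_off <- max(1L, floor(0.05 * n))
  offset <- max(mean(y[(n - n_off + 1L):n]), 0)
  # log-linear regression on offset-subtracted bins that stay positive;
  # if the offset guess swallows the tail, regress on the raw counts
  ysub <- y - offset
  idx <- which(ysub > 0)
  if (length(idx) < 5) {
    ysub <- y
    idx <- which(y > 0)
    offset <- 0
  }
  f <- stats::lm.fit(cbind(1, t[idx]), log(ysub[idx]))
  slope <- f$coefficients[2]
  tau <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(t)) / 3
  amp <- max(exp(f$coefficients[1]), .Machine$double.eps)
  if (n_components == 1) {
    list(a1 = unname(amp), tau1 = unname(tau), offset = offset)
  } else {
    list(a1 = unname(amp) / 2, tau1 = unname(tau) * 1.5,
         a2 = unname(amp) / 2, tau2 = unname(tau) * 0.5, offset = offset)
  }
}

#' Tail-fit an exponential decay model to a TCSPC histogram
#'
#' Fits \eqn{\sum_i a_i e^{-t/\tau_i} + c} to the decay tail by weighted
#' nonlinear least squares (Levenberg-Marquardt), with Poisson (Neyman)
#' weights \eqn{\sigma^2 = \max(\mathrm{counts}, 1)}. Tail fitting starts
#' after the histogram peak, avoiding the rising edge and instrument
#' response; the default window runs from two bins past the peak to the
#' last non-empty bin.
#'
#' @param decay A [decay_curve()].
#' @param n_components 1 (monoexponential) or 2 (biexponential).
#' @param fit_window Optional `c(start_bin, end_bin)` (1-based, inclusive)
#'   overriding the automatic window.
#' @param min_total_counts Minimum total photons required in the window
#'   before fitting is attempted.
#' @return A list of class `lifetime_fit`: `n_components`, `lifetimes_ns`
#'   (decreasing), `amplitudes` (matching order), `offset`, `fit_window`,
#'   `chi2_reduced`, `success`, and `message` on failure. Non-convergence
#'   is reported via `success = FALSE`, not an error.
#' @export
tail_fit <- function(decay, n_components = 1, fit_window = NULL,
                     min_total_counts = 1000) {
  stopifnot(inherits(decay, "decay_curve"))
  if (!n_components %in% c(1, 2)) stop("n_components must be 1 or 2")
  counts <- decay$counts
  n <- length(counts)
  peak <- which.max(counts)
  if (is.null(fit_window)) {
    start <- min(peak + 2L, n)
    end <- max(which(counts > 0), start)
  } else {
    start <- fit_window[1]; end <- fit_window[2]
    if (start < peak)
      stop("fit window must start at or after the histogram peak")
  }
  if (start < 1 || end > n || end <= start)
    stop("invalid fit window")
  n_par <- 2 * n_components + 1
  if (end - start + 1 < 3 * n_par)
    stop("fit window shorter than 3x the parameter count")
  t <- decay$bin_times_ns[start:end]
  y <- counts[start:end]
  if (sum(y) < min_total_counts)
    stop(sprintf("only %.0f photons in the fit window (minimum %d)",
                 sum(y), min_total_counts))
  w <- 1 / pmax(y, 1)
  sw <- sqrt(w)
  start_par <- unlist(tail_fit_start(t, y, n_components))
  model <- if (n_components == 1) {
    function(p) p[["a1"]] * exp(-t / p[["tau1"]]) + p[["offset"]]
  } else {
    function(p) p[["a1"]] * exp(-t / p[["tau1"]]) +
      p[["a2"]] * exp(-t / p[["tau2"]]) + p[["offset"]]
  }
  lower <- if (n_components == 1) c(0, 1e-4, 0) else c(0, 1e-4, 0, 1e-4, 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start_par, lower = lower,
                       fn = function(p) sw * (y - model(p)),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  window <- c(start_bin = start, end_bin = end)
  failed <- inherits(fit, "error")
  # info 5 = iteration limit, 0 = improper input; others indicate the
  # solver stopped because no further improvement was possible
  if (!failed && fit$info %in% c(0L, 5L)) failed <- TRUE
  if (failed) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    return(structure(list(n_components = n_components,
                          lifetimes_ns = rep(NA_real_, n_components),
                          amplitudes = rep(NA_real_, n_components),
                          offset = NA_real_, fit_window = window,
                          chi2_reduced = NA_real_, success = FALSE,
                          message = msg),
                     class = "lifetime_fit"))
  }
  p <- fit$par
  taus <- p[grep("^tau", names(p))]
  amps <- p[grep("^a", names(p))]
  ord <- order(taus, decreasing = TRUE)
  chi2 <- sum(fit$fvec^2) / (length(y) - n_par)
  structure(list(n_components = n_components,
                 lifetimes_ns = unname(taus[ord]),
                 amplitudes = unname(amps[ord]),
                 offset = unname(p[["offset"]]), fit_window = window,
                 chi2_reduced = chi2, success = TRUE, message = NULL),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  if (!x$success) {
    cat("<lifetime_fit> FAILED:", x$message, "\n")
  } else {
    cat(sprintf("<lifetime_fit> %d component(s): tau = %s ns, chi2_red = %.3f\n",
                x$n_components,
                paste(sprintf("%.4f", x$lifetimes_ns), collapse = ", "),
                x$chi2_reduced))
  }
  invisible(x)
}

#' Choose between mono- and bi-exponential decay models
#'
#' Fits both models and returns 2 only when the biexponential fit improves
#' the reduced chi-squared by more than `chi2_improvement_threshold`
#' (relative), mirroring the practice of accepting the single-exponential
#' description unless the data clearly demand a second component.
#'
#' @param decay A [decay_curve()].
#' @param chi2_improvement_threshold Relative reduction in chi2_reduced
#'   required to prefer two components (default 0.2, i.e. 20%).
#' @param ... Passed to [tail_fit()].
#' @return 1 or 2.
#' @export
model_select <- function(decay, chi2_improvement_threshold = 0.2, ...) {
  f1 <- tail_fit(decay, n_components = 1, ...)
  if (!f1$success) stop("monoexponential fit failed: ", f1$message)
  if (is.infinite(chi2_improvement_threshold)) return(1L)
  f2 <- tail_fit(decay, n_components = 2, ...)
  if (!f2$success) return(1L)
  improvement <- (f1$chi2_reduced - f2$chi2_reduced) / f1$chi2_reduced
  if (improvement > chi2_improvement_threshold) 2L else 1L
}

#' FRET efficiency from donor lifetimes
#'
#' E = 100 (1 - tau_DA / tau_D), where tau_DA is the donor lifetime in the
#' presence of acceptor and tau_D the donor-only lifetime. Negative values
#' (tau_DA > tau_D) are reported as-is so that donor-reference variability
#' stays visible; a message flags them.
#'
#' @param tau_DA_ns Donor lifetime with acceptor present, ns.
#' @param tau_D_ns Donor-only lifetime, ns.
#' @return Efficiency in percent.
#' @examples
#' flim_fret_efficiency(2.22, 3.05)  # ~27%
#' @export
flim_fret_efficiency <- function(tau_DA_ns, tau_D_ns) {
  if (any(tau_DA_ns <= 0) || any(tau_D_ns <= 0))
    stop("lifetimes must be positive")
  e <- 100 * (1 - tau_DA_ns / tau_D_ns)
  if (any(e < 0))
    message("negative FRET efficiency: tau_DA exceeds tau_D")
  e
}

#' Per-pixel lifetime map of a FLIM stack
#'
#' Monoexponentially tail-fits each pixel with at least
#' `min_photons_per_pixel` total photons; dimmer pixels are returned as
#' `NA`.
#'
#' @param stack A [flim_stack()].
#' @param min_photons_per_pixel Minimum per-pixel photon total (>= 1).
#' @return A `ny x nx` matrix of fitted lifetimes (ns), `NA` where absent
#'   or where the per-pixel fit failed.
#' @export
lifetime_map <- function(stack, min_photons_per_pixel = 100) {
  stopifnot(inherits(stack, "flim_stack"))
  if (min_photons_per_pixel < 1) stop("min_photons_per_pixel must be >= 1")
  dims <- dim(stack$counts)
  intensity <- flim_intensity(stack)
  out <- matrix(NA_real_, dims[1], dims[2])
  idx <- which(intensity >= min_photons_per_pixel, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    y <- idx[k, 1]; x <- idx[k, 2]
    d <- decay_curve(stack$bin_times_ns, stack$counts[y, x, ])
    f <- tryCatch(tail_fit(d, n_components = 1,
                           min_total_counts = min_photons_per_pixel),
                  error = function(e) NULL)
    if (!is.null(f) && f$success) out[y, x] <- f$lifetimes_ns[1]
  }
  out
}

#' Compare FRET efficiency before and after acceptor photobleaching
#'
#' Destroying the acceptor should return the donor lifetime to its
#' donor-only value; the efficiency computed after bleaching therefore
#' reports residual (non-FRET) lifetime differences.
#'
#' @param pre_fit,post_fit Successful [tail_fit()] results before and after
#'   bleaching.
#' @param tau_D_ns Donor-only reference lifetime, ns.
#' @return A list with `E_pre`, `E_post` and `delta_E` (percentage points,
#'   `E_pre - E_post`).
#' @export
photobleach_compare <- function(pre_fit, post_fit, tau_D_ns) {
  stopifnot(inherits(pre_fit, "lifetime_fit"), inherits(post_fit, "lifetime_fit"))
  if (!pre_fit$success || !post_fit$success)
    stop("both fits must have succeeded")
  e_pre <- flim_fret_efficiency(pre_fit$lifetimes_ns[1], tau_D_ns)
  e_post <- flim_fret_efficiency(post_fit$lifetimes_ns[1], tau_D_ns)
  list(E_pre = e_pre, E_post = e_post, delta_E = e_pre - e_post)
}

#' Lifetimes and intensities across acquisition frame blocks
#'
#' Fits each block's decay and tabulates lifetime and total photon count,
#' supporting donor photostability assessments across prolonged
#' acquisitions (stable lifetime with decreasing intensity indicates
#' bleaching without photophysical damage to the remaining fluorophores).
#'
#' @param blocks A list of [decay_curve()] objects (or [flim_stack()]s,
#'   summed over the full frame), ordered by acquisition block.
#' @param ... Passed to [tail_fit()].
#' @return A data.frame with columns `block`, `tau_ns`, `total_counts`,
#'   `chi2_reduced`, `success`.
#' @export
framewise_lifetimes <- function(blocks, ...) {
  if (length(blocks) < 1) stop("need at least one block")
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (inherits(b, "flim_stack")) b <- sum_roi_decay(b)
    stopifnot(inherits(b, "decay_curve"))
    f <- tail_fit(b, n_components = 1, ...)
    data.frame(block = i,
               tau_ns = if (f$success) f$lifetimes_ns[1] else NA_real_,
               total_counts = sum(b$counts),
               chi2_reduced = f$chi2_reduced,
               success = f$success)
  })
  do.call(rbind, rows)
}
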
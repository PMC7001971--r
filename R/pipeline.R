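#' Write a FLIM stack as a multi-page TIFF plus a JSON sidecar
#'
#' One 16-bit TIFF page per time bin; bin-center times go into
#' `<path>.json`.
#'
#' @param stack A [flim_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  mx <- max(1, stack$counts)
  pages <- lapply(seq_along(stack$bin_times_ns),
                  function(b) stack$counts[, , b] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(bin_times_ns = stack$bin_times_ns,
                            count_scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FLIM stack written by [write_flim_stack()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return A [flim_stack()].
#' @export
read_flim_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cube <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (b in seq_along(pages))
    cube[, , b] <- round(pages[[b]] * side$count_scale)
  flim_stack(cube, side$bin_times_ns)
}

write_if_dir <- function(df, output_dir, name) {
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  invisible(NULL)
}

log_run <- function(output_dir, params) {
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    params$fretkit_version <-
      as.character(utils::packageVersion("fretkit"))
    params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(params, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(NULL)
}

#' Batch spectral-FRET pipeline
#'
#' Unmixes each emission scan against the donor and acceptor references
#' and tabulates per-scan component weights, efficiency and fit quality.
#' Scans may be `emission_scan` objects or CSV paths
#' (`wavelength_nm,value`); per-scan failures are logged as warnings and
#' the run continues.
#'
#' @param scans Named list of [emission_scan()] objects or file paths.
#' @param donor_ref,acceptor_ref Reference emission spectra.
#' @param quantum_yield_donor,quantum_yield_acceptor Quantum yields for
#'   the efficiency formula.
#' @param fit_baseline,shift_nm Passed to [linear_unmix()].
#' @param output_dir Optional directory for `spectral_results.csv` and a
#'   JSON run log.
#' @return A data.frame: `scan`, `w_donor`, `w_acceptor`,
#'   `E_percent`, `r_squared` (failed scans omitted).
#' @export
run_spectral_pipeline <- function(scans, donor_ref, acceptor_ref,
                                  quantum_yield_donor = 0.8,
                                  quantum_yield_acceptor = 0.54,
                                  fit_baseline = FALSE, shift_nm = 0,
                                  output_dir = NULL) {
  nm <- names(scans)
  if (is.null(nm)) nm <- paste0("scan_", seq_along(scans))
  rows <- lapply(seq_along(scans), function(i) {
    tryCatch({
      sc <- scans[[i]]
      if (is.character(sc)) {
        s <- read_spectrum(sc, "emission_au")
        sc <- emission_scan(s$wavelength_nm, s$value,
                            excitation_nm = min(s$wavelength_nm) - 20)
      }
      res <- linear_unmix(sc, donor_ref, acceptor_ref,
                          fit_baseline = fit_baseline, shift_nm = shift_nm)
      data.frame(scan = nm[i], w_donor = res$w_donor,
                 w_acceptor = res$w_acceptor,
                 E_percent = spectral_fret_efficiency(
                   res, quantum_yield_donor, quantum_yield_acceptor),
                 r_squared = res$r_squared)
    }, error = function(e) {
      warning(sprintf("scan '%s' skipped: %s", nm[i], conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scan = character(0), w_donor = numeric(0),
                      w_acceptor = numeric(0), E_percent = numeric(0),
                      r_squared = numeric(0))
  write_if_dir(out, output_dir, "spectral_results.csv")
  log_run(output_dir, list(stage = "spectral",
                           quantum_yield_donor = quantum_yield_donor,
                           quantum_yield_acceptor = quantum_yield_acceptor,
                           fit_baseline = fit_baseline, shift_nm = shift_nm))
  out
}

#' Per-cell FLIM-FRET pipeline with group comparison
#'
#' Sums each labeled cell of each FLIM stack into a decay, tail-fits it,
#' converts the lifetime to an efficiency against the donor-only
#' reference, and summarizes each experimental group (mean with a normal
#' 95% confidence interval). When two or more groups are supplied, all
#' pairwise permutation tests on the per-cell lifetimes are reported.
#'
#' @param groups Named list of groups; each group is a list of entries
#'   `list(stack = <flim_stack>, labels = <label matrix>)` (the output of
#'   [gen_flim_stack()] works directly).
#' @param tau_D_ns Donor-only reference lifetime, ns.
#' @param intensity_threshold,min_total_counts Passed to
#'   [sum_roi_decay()] / [tail_fit()].
#' @param n_perm,perm_seed Permutation-test settings for the group
#'   comparisons.
#' @param output_dir Optional directory for CSV outputs and the run log.
#' @return A list with `cells` (per-cell data.frame: `group`, `stack`,
#'   `cell_id`, `tau_ns`, `E_percent`, `chi2_reduced`), `summary`
#'   (per-group mean, sd, n, 95% CI), and `comparisons` (pairwise
#'   permutation p-values on lifetimes; `NULL` with fewer than 2 groups).
#' @export
run_flim_pipeline <- function(groups, tau_D_ns = 3.05,
                              intensity_threshold = 0,
                              min_total_counts = 1000,
                              n_perm = 1e5, perm_seed = NULL,
                              output_dir = NULL) {
  rows <- list()
  for (g in names(groups)) {
    entries <- groups[[g]]
    if (!is.null(entries$stack)) entries <- list(entries)
    for (si in seq_along(entries)) {
      entry <- entries[[si]]
      ids <- sort(unique(entry$labels[entry$labels > 0]))
      for (id in ids) {
        row <- tryCatch({
          d <- sum_roi_decay(entry$stack, entry$labels == id,
                             intensity_threshold)
          f <- tail_fit(d, n_components = 1,
                        min_total_counts = min_total_counts)
          if (!f$success) stop(f$message)
          data.frame(group = g, stack = si, cell_id = id,
                     tau_ns = f$lifetimes_ns[1],
                     E_percent = suppressMessages(
                       flim_fret_efficiency(f$lifetimes_ns[1], tau_D_ns)),
                     chi2_reduced = f$chi2_reduced)
        }, error = function(e) {
          warning(sprintf("group '%s' stack %d cell %d skipped: %s",
                          g, si, id, conditionMessage(e)), call. = FALSE)
          NULL
        })
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  cells <- do.call(rbind, rows)
  if (is.null(cells))
    stop("no cells could be fitted")
  summarize <- function(df) {
    ci <- stats::qt(0.975, df = max(nrow(df) - 1, 1)) *
      stats::sd(df$tau_ns) / sqrt(nrow(df))
    data.frame(group = df$group[1], n_cells = nrow(df),
               mean_tau_ns = mean(df$tau_ns), sd_tau_ns = stats::sd(df$tau_ns),
               ci95_tau_ns = ci, mean_E_percent = mean(df$E_percent))
  }
  summary <- do.call(rbind, lapply(split(cells, cells$group), summarize))
  rownames(summary) <- NULL
  comparisons <- NULL
  gs <- unique(cells$group)
  if (length(gs) >= 2) {
    pairs <- utils::combn(gs, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- cells$tau_ns[cells$group == pairs[1, k]]
      b <- cells$tau_ns[cells$group == pairs[2, k]]
      pt <- permutation_test(a, b, n_perm = n_perm, seed = perm_seed)
      data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                 p_value = pt$p_value, method = pt$method)
    }))
  }
  write_if_dir(cells, output_dir, "flim_cells.csv")
  write_if_dir(summary, output_dir, "flim_summary.csv")
  if (!is.null(comparisons))
    write_if_dir(comparisons, output_dir, "flim_comparisons.csv")
  log_run(output_dir, list(stage = "flim", tau_D_ns = tau_D_ns,
                           intensity_threshold = intensity_threshold,
                           min_total_counts = min_total_counts,
                           n_perm = n_perm, perm_seed = perm_seed))
  list(cells = cells, summary = summary, comparisons = comparisons)
}

#' Per-cell heterogeneity pipeline: slopes and slope histogram
#'
#' Background-subtracts each two-channel image, segments it (unless label
#' masks are supplied), regresses red on green within each cell, and
#' histograms the pooled slopes.
#'
#' @param images List of entries: either [two_channel_image()] objects or
#'   lists `list(image = ..., labels = ...)` with precomputed label masks
#'   (the output of [gen_two_channel_image()] works directly).
#' @param min_pixels Minimum pixels per cell.
#' @param segment_threshold,segment_min_area Passed to [segment_cells()]
#'   when labels are absent.
#' @param bin_width Optional histogram bin width (default
#'   Freedman-Diaconis).
#' @param output_dir Optional directory for CSV outputs and the run log.
#' @return A list with `slopes` (per-cell data.frame including an `image`
#'   column) and `histogram`.
#' @export
run_heterogeneity_pipeline <- function(images, min_pixels = 50,
                                       segment_threshold = NULL,
                                       segment_min_area = 50,
                                       bin_width = NULL, output_dir = NULL) {
  rows <- lapply(seq_along(images), function(i) {
    entry <- images[[i]]
    img <- if (inherits(entry, "two_channel_image")) entry else entry$image
    labels <- if (inherits(entry, "two_channel_image")) NULL else entry$labels
    sub <- background_subtract(img, masks = labels)
    if (is.null(labels))
      labels <- segment_cells(sub, threshold = segment_threshold,
                              min_area = segment_min_area)
    s <- image_slopes(sub, labels, min_pixels = min_pixels)
    if (nrow(s) > 0) s$image <- i
    s
  })
  slopes <- do.call(rbind, rows)
  if (is.null(slopes) || nrow(slopes) == 0)
    stop("no cells yielded slopes")
  hist <- slope_histogram(slopes, bin_width = bin_width)
  write_if_dir(slopes, output_dir, "slopes.csv")
  write_if_dir(hist, output_dir, "slope_histogram.csv")
  log_run(output_dir, list(stage = "heterogeneity", min_pixels = min_pixels,
                           segment_min_area = segment_min_area))
  list(slopes = slopes, histogram = hist)
}
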
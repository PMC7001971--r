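#' Construct a two-channel confocal image
#'
#' Paired green (donor) and red (acceptor) intensity images of the same
#' field, collected sequentially so the channels are free of bleed-through.
#'
#' @param green,red Non-negative numeric matrices of equal dimensions.
#' @param bit_depth Optional acquisition bit depth (metadata only).
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(green, red, bit_depth = NA_integer_) {
  green <- as.matrix(green); red <- as.matrix(red)
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must have identical dimensions")
  if (length(green) == 0) stop("image is empty")
  if (any(!is.finite(green)) || any(!is.finite(red)))
    stop("image contains non-finite values")
  if (any(green < 0) || any(red < 0))
    stop("intensities must be non-negative")
  structure(list(green = green, red = red, bit_depth = bit_depth),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px\n",
              nrow(x$green), ncol(x$green)))
  invisible(x)
}

#' Read a two-channel image from TIFF file(s)
#'
#' Accepts either one two-page TIFF (page 1 = green, page 2 = red) or two
#' single-page TIFFs.
#'
#' @param green_path Path to the green-channel (or two-page) TIFF.
#' @param red_path Path to the red-channel TIFF, or `NULL` if
#'   `green_path` holds both pages.
#' @return A [two_channel_image()].
#' @export
read_two_channel_tiff <- function(green_path, red_path = NULL) {
  pages <- tiff::readTIFF(green_path, all = TRUE, as.is = TRUE)
  if (is.null(red_path)) {
    if (length(pages) < 2)
      stop("expected a two-page TIFF when red_path is not given")
    two_channel_image(pages[[1]], pages[[2]])
  } else {
    red <- tiff::readTIFF(red_path, all = TRUE, as.is = TRUE)
    two_channel_image(pages[[1]], red[[1]])
  }
}

#' Write a two-channel image as a two-page 16-bit TIFF
#'
#' @param img A [two_channel_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_two_channel_tiff <- function(img, path) {
  stopifnot(inherits(img, "two_channel_image"))
  mx <- max(1, img$green, img$red)
  tiff::writeTIFF(list(img$green / mx, img$red / mx), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Subtract per-channel background from a two-channel image
#'
#' The background level of each channel is estimated as the median of the
#' pixels outside all cell masks (default), or as the channel's 5th
#' percentile when no masks are available, then subtracted; negative
#' results are clipped to zero.
#'
#' @param img A [two_channel_image()].
#' @param masks Optional labeled mask matrix (or logical matrix) marking
#'   cell pixels; background is estimated outside it.
#' @param method `"outside_masks"` (requires `masks`) or `"percentile"`.
#' @param percentile Quantile used by the percentile method.
#' @return A background-subtracted [two_channel_image()].
#' @export
background_subtract <- function(img, masks = NULL,
                                method = c("outside_masks", "percentile"),
                                percentile = 0.05) {
  stopifnot(inherits(img, "two_channel_image"))
  method <- match.arg(method)
  if (method == "outside_masks" && is.null(masks)) method <- "percentile"
  bg <- function(channel) {
    if (method == "outside_masks") {
      outside <- channel[masks == 0]
      if (length(outside) == 0) stop("background region is empty")
      stats::median(outside)
    } else {
      stats::quantile(channel, percentile, names = FALSE)
    }
  }
  two_channel_image(pmax(img$green - bg(img$green), 0),
                    pmax(img$red - bg(img$red), 0),
                    bit_depth = img$bit_depth)
}

#' Segment cells by intensity threshold and connected components
#'
#' An automated surrogate for manually drawn regions of interest: pixels
#' where `green + red` exceeds the threshold are grouped into 8-connected
#' components, small components are discarded, and labels are assigned
#' deterministically in raster order of each component's first pixel.
#' Externally produced label masks can be used anywhere this function's
#' output is accepted.
#'
#' @param img A [two_channel_image()].
#' @param threshold Intensity threshold on the channel sum; default is
#'   twice the median of the summed image (a rough foreground cut).
#' @param min_area Minimum component area in pixels.
#' @return An integer label matrix (0 = background); zero labeled cells is
#'   a valid outcome.
#' @export
segment_cells <- function(img, threshold = NULL, min_area = 50) {
  stopifnot(inherits(img, "two_channel_image"))
  total <- img$green + img$red
  if (is.null(threshold)) threshold <- 2 * stats::median(total)
  fg <- total > threshold
  if (!any(fg)) return(matrix(0L, nrow(total), ncol(total)))
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(total), ncol(total))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  # relabel 1..k by raster order (row-major) of first occurrence
  flat <- as.vector(t(lab))
  first <- vapply(keep, function(k) match(k, flat), 0L)
  remap <- integer(max(lab, 1))
  remap[keep[order(first)]] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Red-versus-green pixel intensity slope of one cell
#'
#' Ordinary least-squares regression of the red-channel intensity on the
#' green-channel intensity over the cell's pixels (after background
#' subtraction). In a tandem donor-acceptor construct every cell should
#' show the same red/green ratio, so the spread of this slope across cells
#' measures expression heterogeneity, and cells with immature (dark)
#' acceptors show slopes near zero.
#'
#' @param img A background-subtracted [two_channel_image()].
#' @param mask Logical matrix selecting the cell's pixels.
#' @param cell_id Identifier carried into the output.
#' @param min_pixels Minimum pixel count required for a stable slope.
#' @return A one-row data.frame: `cell_id`, `slope`, `intercept`,
#'   `r_squared`, `n_pixels`.
#' @export
cell_intensity_slope <- function(img, mask, cell_id = 1L, min_pixels = 50) {
  stopifnot(inherits(img, "two_channel_image"))
  mask <- mask > 0
  if (!identical(dim(mask), dim(img$green)))
    stop("mask shape must match the image")
  g <- img$green[mask]; r <- img$red[mask]
  if (length(g) < min_pixels)
    stop(sprintf("cell %s has %d pixels (minimum %d)",
                 cell_id, length(g), min_pixels))
  if (stats::var(g) == 0)
    stop("zero variance in the green channel within the mask")
  fit <- stats::lm(r ~ g)
  tss <- sum((r - mean(r))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  data.frame(cell_id = cell_id,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = r2,
             n_pixels = length(g))
}

#' Per-cell slopes for every labeled cell in an image
#'
#' Applies [cell_intensity_slope()] to each label of a segmentation;
#' cells failing the pixel minimum or with degenerate green intensities
#' are skipped.
#'
#' @param img A background-subtracted [two_channel_image()].
#' @param labels Integer label matrix from [segment_cells()] or external
#'   masks.
#' @param min_pixels Minimum pixels per cell.
#' @return A data.frame of slope records (possibly zero rows).
#' @export
image_slopes <- function(img, labels, min_pixels = 50) {
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    tryCatch(cell_intensity_slope(img, labels == id, cell_id = id,
                                  min_pixels = min_pixels),
             error = function(e) NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), slope = numeric(0),
                      intercept = numeric(0), r_squared = numeric(0),
                      n_pixels = integer(0))
  out
}

#' Histogram of per-cell slopes
#'
#' Bins the slopes of a cell cohort. The default bin width follows the
#' Freedman-Diaconis rule (2 IQR / n^(1/3)); a fixed width can be given
#' instead.
#'
#' @param records Data.frame with a `slope` column (e.g. from
#'   [image_slopes()]).
#' @param bin_width Optional fixed bin width overriding Freedman-Diaconis.
#' @return A data.frame with `bin_left`, `bin_right`, `bin_mid`, `count`.
#' @export
slope_histogram <- function(records, bin_width = NULL) {
  s <- records$slope
  if (length(s) < 1) stop("need at least one slope record")
  if (is.null(bin_width)) {
    iqr <- stats::IQR(s)
    bin_width <- if (iqr > 0) 2 * iqr / length(s)^(1 / 3) else NULL
  }
  breaks <- if (is.null(bin_width)) {
    "FD"
  } else {
    lo <- floor(min(s) / bin_width) * bin_width
    seq(lo, max(s) + bin_width, by = bin_width)
  }
  h <- graphics::hist(s, breaks = breaks, right = FALSE, plot = FALSE)
  data.frame(bin_left = utils::head(h$breaks, -1),
             bin_right = utils::tail(h$breaks, -1),
             bin_mid = h$mids, count = h$counts)
}

#' Mode of a slope histogram (midpoint of the fullest bin)
#'
#' @param histogram Output of [slope_histogram()].
#' @return The `bin_mid` of the bin with the highest count.
#' @export
histogram_mode <- function(histogram) {
  histogram$bin_mid[which.max(histogram$count)]
}
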
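#' Convert raw CT numbers to Hounsfield units
#'
#' Applies the scanner calibration `HU = CT * 2.26625 - 190`, the linear
#' transform mapping raw CT numbers onto the Hounsfield scale (water at 0 HU,
#' fat negative, lean muscle positive).
#'
#' @param values Numeric vector of raw CT numbers. All elements must be finite.
#' @param slope,intercept Calibration coefficients. Defaults are the mid-thigh
#'   protocol values; override them for a differently calibrated scanner.
#' @return Numeric vector of HU values, same length and order as `values`.
#' @examples
#' ct_to_hu(c(0, 100))
#' @export
ct_to_hu <- function(values, slope = 2.26625, intercept = -190) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite CT number at index %d", bad[[1L]]))
  }
  values * slope + intercept
}

#' Construct a pixel set
#'
#' A pixel set holds every soft-tissue pixel value of one subject's single
#' mid-thigh CT cross-section, tagged with the unit of the values so the
#' CT-number-to-HU calibration is applied exactly once.
#'
#' @param values Non-empty numeric vector of pixel values.
#' @param subject_id Identifier carried through all per-subject outputs.
#' @param unit Either `"hounsfield"` (values are already HU) or `"ct_number"`
#'   (raw scanner values, still to be calibrated via [ct_to_hu()]).
#' @param pixel_area In-plane area of one pixel in mm^2; converts pixel counts
#'   to cross-sectional areas.
#' @return An object of class `pixel_set`.
#' @seealso [as_hu()], [build_histogram()], [standard_metrics()]
#' @export
pixel_set <- function(values, subject_id = "subject",
                      unit = c("hounsfield", "ct_number"), pixel_area = 1.0) {
  unit <- match.arg(unit)
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector")
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite pixel value at index %d", bad[[1L]]))
  }
  if (!is.numeric(pixel_area) || length(pixel_area) != 1L || pixel_area <= 0) {
    stop("`pixel_area` must be a single positive number")
  }
  structure(
    list(subject_id = as.character(subject_id), values = as.numeric(values),
         unit = unit, pixel_area = as.numeric(pixel_area)),
    class = "pixel_set"
  )
}

#' @export
print.pixel_set <- function(x, ...) {
  cat(sprintf("<pixel_set> subject %s: %d pixels [%s], pixel area %g mm^2\n",
              x$subject_id, length(x$values), x$unit, x$pixel_area))
  invisible(x)
}

#' Coerce a pixel set to Hounsfield units
#'
#' Applies [ct_to_hu()] when the set is in raw CT numbers; a set already in
#' HU is returned unchanged, so the calibration is never applied twice.
#'
#' @param pixels A [pixel_set()].
#' @inheritParams ct_to_hu
#' @return A `pixel_set` with `unit = "hounsfield"`.
#' @export
as_hu <- function(pixels, slope = 2.26625, intercept = -190) {
  stopifnot(inherits(pixels, "pixel_set"))
  if (pixels$unit == "hounsfield") return(pixels)
  pixels$values <- ct_to_hu(pixels$values, slope = slope, intercept = intercept)
  pixels$unit <- "hounsfield"
  pixels
}

#' Bin a pixel set into a fixed-width HU histogram
#'
#' Bins the HU values of one subject into `n_bins` uniform bins over
#' `hu_range`. The default 128 bins over \[-200, 200\] HU cover the three
#' soft-tissue domains (fat, loose connective tissue, muscle). Bins are
#' half-open `[left, right)` with the last bin closed; pixels outside the
#' range are counted and reported in `n_out_of_range`, never silently dropped.
#'
#' @param pixels A [pixel_set()]; raw CT numbers are calibrated first.
#' @param n_bins Number of bins, at least 8.
#' @param hu_range Length-2 ascending numeric, the HU analysis window.
#' @return An object of class `hu_histogram` with fields `bin_edges`
#'   (`n_bins + 1` ascending HU values), `bin_centers`, `counts`, `density`
#'   (`NULL` until [smooth_histogram()] is applied), `total_pixels`,
#'   `n_out_of_range`, `bin_width`, `pixel_area` and `subject_id`.
#' @export
build_histogram <- function(pixels, n_bins = 128L, hu_range = c(-200, 200)) {
  stopifnot(inherits(pixels, "pixel_set"))
  if (length(hu_range) != 2L || !all(is.finite(hu_range))) {
    stop("`hu_range` must be two finite numbers")
  }
  if (hu_range[[2L]] <= hu_range[[1L]]) stop("`hu_range` is inverted or empty")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 8L) stop("`n_bins` must be an integer >= 8")
  pixels <- as_hu(pixels)
  x <- pixels$values
  if (length(x) == 0L) stop("empty pixel set")

  lo <- hu_range[[1L]]; hi <- hu_range[[2L]]
  bw <- (hi - lo) / n_bins
  in_range <- x >= lo & x <= hi
  idx <- pmin(floor((x[in_range] - lo) / bw) + 1, n_bins) # hi falls in last bin
  counts <- tabulate(idx, nbins = n_bins)

  structure(
    list(
      bin_edges = lo + bw * (0:n_bins),
      bin_centers = lo + bw * (seq_len(n_bins) - 0.5),
      counts = as.numeric(counts),
      density = NULL,
      total_pixels = length(x),
      n_out_of_range = sum(!in_range),
      bin_width = bw,
      pixel_area = pixels$pixel_area,
      subject_id = pixels$subject_id
    ),
    class = "hu_histogram"
  )
}

#' @export
print.hu_histogram <- function(x, ...) {
  cat(sprintf(
    "<hu_histogram> subject %s: %d bins over [%g, %g] HU, %d pixels (%d out of range)%s\n",
    x$subject_id, length(x$counts), min(x$bin_edges), max(x$bin_edges),
    x$total_pixels, x$n_out_of_range,
    if (is.null(x$density)) "" else ", smoothed"))
  invisible(x)
}

#' Smooth a histogram into an empirical density curve
#'
#' Applies a Gaussian kernel to the bin counts to obtain the empirical
#' probability density function that the trimodal model is fitted to. The
#' kernel is renormalized at the range edges so that smoothing conserves
#' total mass exactly.
#'
#' @param hist An `hu_histogram` from [build_histogram()].
#' @param bandwidth Kernel standard deviation in HU, or `"auto"` for twice the
#'   bin width. The smoothing algorithm and bandwidth are recorded on the
#'   result (`attr(, "smoothing")`) since they are analysis choices.
#' @param normalize `"density"` scales the curve to unit area (a probability
#'   density); `"counts"` scales it so its integral equals the in-range pixel
#'   count, letting fitted amplitudes proxy tissue areas.
#' @return The histogram with its `density` field filled (per-HU units).
#' @export
smooth_histogram <- function(hist, bandwidth = "auto",
                             normalize = c("density", "counts")) {
  stopifnot(inherits(hist, "hu_histogram"))
  normalize <- match.arg(normalize)
  bw <- hist$bin_width
  if (identical(bandwidth, "auto")) bandwidth <- 2 * bw
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop("`bandwidth` must be a single positive number (HU) or \"auto\"")
  }
  counts <- hist$counts
  n_in <- sum(counts)
  if (n_in <= 0) stop("histogram has no in-range counts to smooth")

  # Column i of W spreads the mass of bin i over neighbouring bins with
  # Gaussian weights; per-column renormalization keeps sum(smoothed) ==
  # sum(counts) even at the range edges.
  d <- outer(hist$bin_centers, hist$bin_centers, "-")
  W <- exp(-d^2 / (2 * bandwidth^2))
  W <- sweep(W, 2L, colSums(W), "/")
  smoothed <- as.numeric(W %*% counts)

  scale <- switch(normalize,
                  density = 1 / (n_in * bw),
                  counts  = 1 / bw)
  hist$density <- smoothed * scale
  attr(hist, "smoothing") <- list(kernel = "gaussian", bandwidth = bandwidth,
                                  normalize = normalize)
  hist
}

#' Write a histogram to CSV
#'
#' @param hist An `hu_histogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "hu_histogram"))
  n <- length(hist$counts)
  df <- data.frame(
    bin_left = hist$bin_edges[seq_len(n)],
    bin_right = hist$bin_edges[seq_len(n) + 1L],
    bin_center = hist$bin_centers,
    count = hist$counts,
    density = if (is.null(hist$density)) NA_real_ else hist$density
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read one subject's pixel values from a delimited text file
#'
#' Expects a one-column numeric file (with or without a header line); this is
#' the per-subject format written by [write_cohort()] and consumed by
#' [run_pipeline()].
#'
#' @param path File path.
#' @param subject_id Subject identifier; defaults to the file name stem.
#' @param unit Unit of the stored values, as in [pixel_set()].
#' @param pixel_area Pixel area in mm^2.
#' @return A [pixel_set()].
#' @export
read_pixel_csv <- function(path, subject_id = NULL,
                           unit = c("hounsfield", "ct_number"),
                           pixel_area = 1.0) {
  unit <- match.arg(unit)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- utils::read.csv(path, header = FALSE, nrows = 1L,
                           stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1L]][1L])))
  df <- utils::read.csv(path, header = has_header)
  pixel_set(as.numeric(df[[1L]]), subject_id = subject_id, unit = unit,
            pixel_area = pixel_area)
}
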
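#' Standard CT soft-tissue metrics
#'
#' Computes the conventional CT muscle-quality metrics used as the comparison
#' baseline for the trimodal model: fat and lean cross-sectional areas and
#' mean lean-tissue attenuation. Lean pixels are those with HU strictly above
#' the fat threshold (the maximal density of fat, -10 HU by default, the
#' upper edge of the fat tissue domain); the remaining in-range pixels count
#' as fat. Areas are pixel counts times the pixel area.
#'
#' @param pixels A [pixel_set()] in HU (raw CT numbers are calibrated first).
#' @param fat_threshold HU value separating fat from lean tissue. The exact
#'   threshold is an analysis choice and is echoed in the result.
#' @param hu_range Soft-tissue analysis window; pixels outside it are
#'   excluded from both areas.
#' @return An object of class `ct_metrics`: `fat_area` and `lean_area`
#'   (mm^2), `lean_mean_hu` (mean HU of lean pixels, `NA` with
#'   `lean_defined = FALSE` when no pixel exceeds the threshold),
#'   `avg_hu` (mean over all in-range pixels), `fat_threshold`,
#'   `n_in_range`, and `subject_id`.
#' @examples
#' p <- pixel_set(c(-50, -20, 30, 60))
#' standard_metrics(p)
#' @export
standard_metrics <- function(pixels, fat_threshold = -10,
                             hu_range = c(-200, 200)) {
  stopifnot(inherits(pixels, "pixel_set"))
  if (!is.numeric(fat_threshold) || length(fat_threshold) != 1L ||
      !is.finite(fat_threshold)) {
    stop("`fat_threshold` must be a single finite HU value")
  }
  pixels <- as_hu(pixels)
  x <- pixels$values
  x <- x[x >= hu_range[[1L]] & x <= hu_range[[2L]]]
  if (length(x) == 0L) stop("no pixels inside the HU analysis range")

  lean <- x[x > fat_threshold]
  n_lean <- length(lean)
  structure(
    list(
      fat_area = (length(x) - n_lean) * pixels$pixel_area,
      lean_area = n_lean * pixels$pixel_area,
      lean_mean_hu = if (n_lean > 0L) mean(lean) else NA_real_,
      lean_defined = n_lean > 0L,
      avg_hu = mean(x),
      fat_threshold = fat_threshold,
      n_in_range = length(x),
      subject_id = pixels$subject_id
    ),
    class = "ct_metrics"
  )
}

#' @export
print.ct_metrics <- function(x, ...) {
  cat(sprintf(
    "<ct_metrics> subject %s: fat %.1f mm^2, lean %.1f mm^2, lean mean %s HU, avg %.2f HU (threshold %g HU)\n",
    x$subject_id, x$fat_area, x$lean_area,
    if (x$lean_defined) sprintf("%.2f", x$lean_mean_hu) else "undefined",
    x$avg_hu, x$fat_threshold))
  invisible(x)
}

#' Average soft-tissue attenuation
#'
#' The whole-section mean HU over all in-range soft-tissue pixels, the
#' simplest conventional muscle-quality metric (more negative values indicate
#' a shift of the distribution toward fat).
#'
#' @inheritParams standard_metrics
#' @return Mean HU, a single number.
#' @export
average_hu <- function(pixels, hu_range = c(-200, 200)) {
  stopifnot(inherits(pixels, "pixel_set"))
  pixels <- as_hu(pixels)
  x <- pixels$values
  x <- x[x >= hu_range[[1L]] & x <= hu_range[[2L]]]
  if (length(x) == 0L) stop("no pixels inside the HU analysis range")
  mean(x)
}
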
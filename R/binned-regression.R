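#' Aggregate imaging parameters within covariate bins
#'
#' For one discretized clinical covariate, computes the per-bin mean of the
#' covariate (the bin representative, x) and the per-bin mean of every
#' imaging parameter (y), producing the (x, y) series that the binned
#' regressions are fitted to. Subjects with a missing covariate or parameter
#' value are dropped from the affected series; the drop count is recorded.
#'
#' @param assignment A `bin_assignment` (from [kmeans_1d()] or
#'   [equal_frequency_bins()]) or a plain integer label vector.
#' @param covariate Per-subject covariate values, aligned with the labels.
#' @param parameters Data frame of per-subject imaging parameters (numeric
#'   columns; a `subject_id` column is ignored), aligned with the labels.
#' @param covariate_name Label carried into the series.
#' @return A named list of `binned_series` objects, one per parameter column:
#'   each has `covariate_name`, `parameter`, `x`, `y`, `bin_n` and
#'   `n_dropped`, with bins ordered by ascending x.
#' @export
aggregate_bins <- function(assignment, covariate, parameters,
                           covariate_name = "covariate") {
  labels <- if (inherits(assignment, "bin_assignment")) assignment$labels else
    as.integer(assignment)
  stopifnot(length(labels) == length(covariate),
            length(labels) == nrow(parameters))
  cols <- names(parameters)[vapply(parameters, is.numeric, logical(1L))]
  cols <- setdiff(cols, "subject_id")
  if (length(cols) == 0L) stop("`parameters` has no numeric parameter columns")

  out <- list()
  for (col in cols) {
    ok <- !is.na(labels) & !is.na(covariate) & !is.na(parameters[[col]])
    lab <- labels[ok]
    bins <- sort(unique(lab))
    empty <- setdiff(seq_len(max(labels, na.rm = TRUE)), bins)
    if (length(empty) > 0L) {
      stop(sprintf("bin %d is empty after joining parameter `%s`",
                   empty[[1L]], col))
    }
    x <- vapply(bins, function(b) mean(covariate[ok][lab == b]), numeric(1L))
    y <- vapply(bins, function(b) mean(parameters[[col]][ok][lab == b]),
                numeric(1L))
    n <- vapply(bins, function(b) sum(lab == b), numeric(1L))
    o <- order(x)
    out[[col]] <- structure(
      list(covariate_name = covariate_name, parameter = col,
           x = x[o], y = y[o], bin_n = as.integer(n[o]),
           n_dropped = sum(!ok)),
      class = "binned_series")
  }
  out
}

#' Simple linear regression on a binned series
#'
#' Ordinary least squares of the per-bin imaging-parameter means on the
#' per-bin covariate representatives, with the covariate on the independent
#' axis. Reports the coefficient of determination and the two-sided p-value
#' of the slope.
#'
#' @param series A `binned_series` from [aggregate_bins()], or any list with
#'   numeric `x` and `y` of equal length >= 3.
#' @return A list of class `binned_lm`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `k` (number of bins), `covariate`, `parameter`.
#' @export
linear_fit <- function(series) {
  x <- series$x; y <- series$y
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  k <- length(x)
  if (k < 3L) stop("at least 3 bins are required for a linear fit")
  if (stats::var(x) == 0) stop("covariate has zero variance across bins")

  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  # slope t-test; a numerically perfect fit gets the smallest positive p
  p_val <- if (r2 >= 1) .Machine$double.xmin
           else if (r2 == 0) 1
           else 2 * stats::pt(sqrt(r2 * (k - 2) / (1 - r2)), df = k - 2,
                              lower.tail = FALSE)
  structure(
    list(slope = unname(stats::coef(fit)[[2L]]),
         intercept = unname(stats::coef(fit)[[1L]]),
         r_squared = r2,
         p_value = p_val,
         k = k,
         covariate = series$covariate_name %||% "x",
         parameter = series$parameter %||% "y"),
    class = "binned_lm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select high-fidelity imaging parameters
#'
#' Applies the correlation-fidelity selection rule: an imaging parameter is
#' retained for a covariate when its binned simple regression explains at
#' least `threshold` of the variance. The comparison quantity defaults to
#' the coefficient of determination R^2; `quantity = "abs_r"` applies the
#' rule to |R| instead.
#'
#' @param results Data frame with columns `covariate`, `parameter`,
#'   `r_squared` (e.g. stacked [linear_fit()] results, see
#'   [correlate_cohort()]).
#' @param threshold Selection threshold, default 0.85; selection uses `>=`.
#' @param quantity `"r_squared"` (default) or `"abs_r"`.
#' @return A list: `selected` (subset of `results` rows passing the rule)
#'   and `incidence` (parameter x covariate logical matrix, the assembly
#'   table of parameters with high correlation fidelity).
#' @export
select_high_fidelity <- function(results, threshold = 0.85,
                                 quantity = c("r_squared", "abs_r")) {
  quantity <- match.arg(quantity)
  stopifnot(is.data.frame(results),
            all(c("covariate", "parameter", "r_squared") %in% names(results)))
  val <- switch(quantity, r_squared = results$r_squared,
                abs_r = sqrt(results$r_squared))
  keep <- val >= threshold
  selected <- results[keep, , drop = FALSE]

  params <- unique(results$parameter)
  covs <- unique(results$covariate)
  incidence <- matrix(FALSE, nrow = length(params), ncol = length(covs),
                      dimnames = list(params, covs))
  if (nrow(selected) > 0L) {
    incidence[cbind(match(selected$parameter, params),
                    match(selected$covariate, covs))] <- TRUE
  }
  list(selected = selected, incidence = incidence, threshold = threshold,
       quantity = quantity)
}

#' Multiple regression of a covariate on selected imaging parameters
#'
#' Ordinary least squares of the per-bin covariate representative on the
#' per-bin means of the selected imaging parameters, with an overall F-test
#' from the one-way ANOVA decomposition of the regression.
#'
#' @param x Numeric vector of per-bin covariate representatives (length k).
#' @param predictors Numeric matrix or data frame, k rows by p columns of
#'   per-bin parameter means; k must exceed p + 1.
#' @return A list of class `binned_mlm`: `coefficients` (intercept first),
#'   `multiple_r` (multiple correlation coefficient), `r_squared`,
#'   `f_statistic`, `p_value`, `df` (numerator, denominator), and `anova`
#'   (regression/residual sum-of-squares table).
#' @export
multiple_fit <- function(x, predictors) {
  X <- as.matrix(predictors)
  stopifnot(is.numeric(x), is.numeric(X))
  k <- length(x)
  p <- ncol(X)
  if (nrow(X) != k) stop("`x` and `predictors` must have the same number of bins")
  if (k <= p + 1L) stop("need more bins than predictors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(p))

  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    dropped <- setdiff(seq_len(p + 1L), qrX$pivot[seq_len(qrX$rank)]) - 1L
    stop(sprintf("predictor matrix is rank deficient; collinear columns: %s",
                 paste(colnames(X)[dropped], collapse = ", ")))
  }

  df <- data.frame(.y = x, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((x - mean(x))^2)
  df1 <- p
  df2 <- k - p - 1L
  r2 <- max(0, min(1, 1 - ss_res / ss_tot))
  fstat <- ((ss_tot - ss_res) / df1) / (ss_res / df2)
  p_val <- if (!is.finite(fstat)) .Machine$double.xmin
           else stats::pf(fstat, df1, df2, lower.tail = FALSE)

  structure(
    list(coefficients = stats::coef(fit),
         multiple_r = sqrt(r2),
         r_squared = r2,
         f_statistic = fstat,
         p_value = max(p_val, .Machine$double.xmin),
         df = c(numerator = df1, denominator = df2),
         anova = data.frame(
           source = c("regression", "residual", "total"),
           ss = c(ss_tot - ss_res, ss_res, ss_tot),
           df = c(p, k - p - 1L, k - 1L))),
    class = "binned_mlm")
}

#' @export
print.binned_mlm <- function(x, ...) {
  cat(sprintf("<binned_mlm> multiple R = %.4f, F(%d, %d) = %.3f, p = %.3g\n",
              x$multiple_r, x$df[[1L]], x$df[[2L]], x$f_statistic, x$p_value))
  invisible(x)
}
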
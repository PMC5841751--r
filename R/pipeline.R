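#' Fit one subject end to end
#'
#' Histogram construction, smoothing, trimodal fit and standard CT metrics
#' for a single pixel set, returned as one row of the cohort parameter table.
#'
#' @param pixels A [pixel_set()].
#' @param n_bins,hu_range Histogram settings (see [build_histogram()]).
#' @param bandwidth,normalize Smoothing settings (see [smooth_histogram()]).
#' @param fat_threshold Fat/lean threshold (see [standard_metrics()]).
#' @param domains A [tissue_domains()] object.
#' @param n_restarts,tol,seed Fit settings (see [fit_ntra()]).
#' @return One-row data frame: subject_id, the 11 trimodal parameters,
#'   `fit_r_squared`, `converged`, and the standard CT metrics (`fat_area_mm2`,
#'   `lean_area_mm2`, `lean_mean_hu`, `avg_hu`).
#' @export
fit_subject <- function(pixels, n_bins = 128L, hu_range = c(-200, 200),
                        bandwidth = "auto", normalize = "density",
                        fat_threshold = -10, domains = tissue_domains(),
                        n_restarts = 2L, tol = 1e-10, seed = NULL) {
  hist <- smooth_histogram(build_histogram(pixels, n_bins, hu_range),
                           bandwidth = bandwidth, normalize = normalize)
  fit <- fit_ntra(hist, domains = domains, n_restarts = n_restarts,
                  tol = tol, seed = seed)
  met <- standard_metrics(pixels, fat_threshold = fat_threshold,
                          hu_range = hu_range)
  data.frame(subject_id = pixels$subject_id,
             t(ntra_flatten(fit$params)),
             fit_r_squared = fit$r_squared, converged = fit$converged,
             fat_area_mm2 = met$fat_area, lean_area_mm2 = met$lean_area,
             lean_mean_hu = met$lean_mean_hu, avg_hu = met$avg_hu,
             stringsAsFactors = FALSE)
}

#' Fit every subject of a cohort
#'
#' Applies [fit_subject()] to a list of pixel sets. Subjects whose fit fails
#' are skipped with a warning and recorded in the `failures` attribute; more
#' than `max_failure_rate` of the cohort failing is an error.
#'
#' @param pixel_sets Named list of [pixel_set()] objects.
#' @param ... Passed to [fit_subject()].
#' @param max_failure_rate Maximum tolerated fraction of failed subjects.
#' @return Data frame with one row per successfully fitted subject.
#' @export
fit_cohort <- function(pixel_sets, ..., max_failure_rate = 0.1) {
  rows <- list()
  failures <- character(0L)
  for (ps in pixel_sets) {
    row <- tryCatch(fit_subject(ps, ...), error = function(e) {
      warning(sprintf("subject %s skipped: %s", ps$subject_id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(row)) failures <- c(failures, ps$subject_id)
    else rows[[length(rows) + 1L]] <- row
  }
  if (length(failures) > max_failure_rate * length(pixel_sets)) {
    stop(sprintf("%d of %d subjects failed to fit (limit %.0f%%)",
                 length(failures), length(pixel_sets),
                 100 * max_failure_rate))
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Binned correlation analysis of imaging parameters against covariates
#'
#' For each clinical covariate: discretizes it by exact 1-D k-means (k from
#' Sturges' formula unless overridden), aggregates every imaging parameter
#' within bins, fits the per-parameter simple regressions, applies the
#' high-fidelity selection rule, and runs the multiple regression of the
#' covariate on the selected parameters (strongest first; predictors that
#' would make the design rank deficient or exceed the bin count are dropped
#' and recorded in `dropped_collinear`).
#'
#' @param params Per-subject imaging parameter table with a `subject_id`
#'   column (e.g. from [fit_cohort()]).
#' @param covariates Covariate table with `subject_id` and the columns named
#'   in `covariate_names`.
#' @param covariate_names Covariates to analyze; defaults to every numeric
#'   column except age.
#' @param k Bin-count override; `NULL` applies Sturges' formula per
#'   covariate to its non-missing count.
#' @param threshold,quantity Selection rule (see [select_high_fidelity()]).
#' @param method Discretization method, `"kmeans_1d"` or `"equal_frequency"`.
#' @param max_predictors Cap on the number of predictors entering each
#'   multiple regression; `NULL` uses `floor((k - 1) / 2)` so the overall
#'   F-test keeps residual degrees of freedom (with k bins a saturated
#'   design would leave df = 1 and no power). Predictors enter in order of
#'   decreasing simple-fit fidelity.
#' @return A list of class `cohort_correlation`: `regressions` (tidy data
#'   frame: covariate, parameter, k, slope, intercept, r_squared, p_value),
#'   `selection` (see [select_high_fidelity()]), `multiple` (named list of
#'   [multiple_fit()] results per covariate with at least one selected
#'   parameter), `bins` (per-covariate bin summary), and `n_tests`.
#' @export
correlate_cohort <- function(params, covariates,
                             covariate_names = NULL, k = NULL,
                             threshold = 0.85, quantity = "r_squared",
                             method = c("kmeans_1d", "equal_frequency"),
                             max_predictors = NULL) {
  method <- match.arg(method)
  stopifnot("subject_id" %in% names(params),
            "subject_id" %in% names(covariates))
  if (is.null(covariate_names)) {
    num <- names(covariates)[vapply(covariates, is.numeric, logical(1L))]
    covariate_names <- setdiff(num, c("subject_id", "age"))
  }
  merged <- merge(covariates, params, by = "subject_id", sort = TRUE)
  param_cols <- setdiff(names(params)[vapply(params, is.numeric, logical(1L))],
                        c("subject_id", "fit_r_squared"))

  reg_rows <- list()
  multiple <- list()
  bin_rows <- list()
  for (cv in covariate_names) {
    x <- merged[[cv]]
    ok <- !is.na(x)
    kk <- if (is.null(k)) sturges(sum(ok))$k else as.integer(k)
    asg <- switch(method,
                  kmeans_1d = kmeans_1d(x[ok], kk),
                  equal_frequency = equal_frequency_bins(x[ok], kk))
    series <- aggregate_bins(asg, x[ok],
                             merged[ok, param_cols, drop = FALSE],
                             covariate_name = cv)
    fits <- lapply(series, linear_fit)
    reg_rows[[cv]] <- data.frame(
      covariate = cv, parameter = param_cols, k = kk,
      slope = vapply(fits, `[[`, numeric(1L), "slope"),
      intercept = vapply(fits, `[[`, numeric(1L), "intercept"),
      r_squared = vapply(fits, `[[`, numeric(1L), "r_squared"),
      p_value = vapply(fits, `[[`, numeric(1L), "p_value"),
      row.names = NULL, stringsAsFactors = FALSE)
    bin_rows[[cv]] <- data.frame(
      covariate = cv, bin = seq_len(kk), n = asg$bin_sizes,
      mean = asg$representatives, stringsAsFactors = FALSE)
    attr(series, "x") <- series[[1L]]$x
    multiple[[cv]] <- series # placeholder, replaced after selection
  }
  regressions <- do.call(rbind, reg_rows)
  rownames(regressions) <- NULL
  selection <- select_high_fidelity(regressions, threshold = threshold,
                                    quantity = quantity)

  mlm <- list()
  for (cv in covariate_names) {
    sel_rows <- selection$selected[selection$selected$covariate == cv, ]
    if (nrow(sel_rows) == 0L) next
    # strongest predictors first, then keep the model identifiable: cap the
    # predictor count below the bin count and drop collinear columns
    sel <- sel_rows$parameter[order(sel_rows$r_squared, decreasing = TRUE)]
    series <- multiple[[cv]]
    x <- series[[sel[[1L]]]]$x
    p_max <- if (is.null(max_predictors)) max(1L, (length(x) - 1L) %/% 2L)
             else min(as.integer(max_predictors), length(x) - 2L)
    keep <- character(0L)
    dropped <- character(0L)
    for (cand in sel) {
      if (length(keep) >= p_max) break
      trial <- vapply(series[c(keep, cand)], `[[`, numeric(length(x)), "y")
      trial <- matrix(trial, ncol = length(keep) + 1L)
      if (qr(cbind(1, trial))$rank == ncol(trial) + 1L) keep <- c(keep, cand)
      else dropped <- c(dropped, cand)
    }
    X <- vapply(series[keep], `[[`, numeric(length(x)), "y")
    X <- matrix(X, ncol = length(keep), dimnames = list(NULL, keep))
    mlm[[cv]] <- tryCatch(multiple_fit(x, X), error = function(e) {
      warning(sprintf("multiple regression for %s failed: %s", cv,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(mlm[[cv]])) mlm[[cv]]$dropped_collinear <- dropped
  }

  structure(
    list(regressions = regressions, selection = selection,
         multiple = Filter(Negate(is.null), mlm),
         bins = do.call(rbind, bin_rows), n_tests = nrow(regressions)),
    class = "cohort_correlation"
  )
}

#' @export
print.cohort_correlation <- function(x, ...) {
  cat(sprintf("<cohort_correlation> %d simple regressions over %d covariates; %d pass the %.2f rule\n",
              x$n_tests, length(unique(x$regressions$covariate)),
              nrow(x$selection$selected), x$selection$threshold))
  invisible(x)
}

#' Pipeline configuration
#'
#' Validated bundle of every setting of [run_pipeline()]. All numeric
#' settings are checked against the preconditions of the stage that consumes
#' them before any computation starts.
#'
#' @param pixel_dir Directory of per-subject single-column pixel CSVs.
#' @param covariate_file Covariate table CSV (subject_id, age, sex, gsn,
#'   gsf, tug, str, schol, bmi).
#' @param output_dir Directory for all outputs.
#' @param unit Unit of the stored pixel values (see [pixel_set()]).
#' @param pixel_area Pixel area, mm^2.
#' @param n_bins,hu_range,bandwidth,normalize Histogram and smoothing
#'   settings.
#' @param fat_threshold Fat/lean threshold, HU (a mandatory, logged choice).
#' @param n_restarts,tol Fit settings.
#' @param k Bin-count override for discretization (`NULL` = Sturges).
#' @param method Discretization method.
#' @param threshold,quantity Selection rule settings.
#' @param seed Top-level seed; every stochastic stage derives from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_dir, covariate_file, output_dir,
                            unit = "hounsfield", pixel_area = 1.0,
                            n_bins = 128L, hu_range = c(-200, 200),
                            bandwidth = "auto", normalize = "density",
                            fat_threshold = -10, n_restarts = 2L,
                            tol = 1e-10, k = NULL, method = "kmeans_1d",
                            threshold = 0.85, quantity = "r_squared",
                            seed = 1L) {
  if (length(hu_range) != 2L || hu_range[[2L]] <= hu_range[[1L]]) {
    stop("`hu_range` is inverted or empty")
  }
  if (as.integer(n_bins) < 8L) stop("`n_bins` must be >= 8")
  if (!identical(bandwidth, "auto") &&
      (!is.numeric(bandwidth) || bandwidth <= 0)) {
    stop("`bandwidth` must be positive or \"auto\"")
  }
  if (!is.null(k) && as.integer(k) < 1L) stop("`k` must be >= 1")
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  cfg <- list(pixel_dir = pixel_dir, covariate_file = covariate_file,
              output_dir = output_dir, unit = match.arg(unit, c("hounsfield", "ct_number")),
              pixel_area = pixel_area, n_bins = as.integer(n_bins),
              hu_range = as.numeric(hu_range), bandwidth = bandwidth,
              normalize = match.arg(normalize, c("density", "counts")),
              fat_threshold = fat_threshold,
              n_restarts = as.integer(n_restarts), tol = tol,
              k = if (is.null(k)) NULL else as.integer(k),
              method = match.arg(method, c("kmeans_1d", "equal_frequency")),
              threshold = threshold,
              quantity = match.arg(quantity, c("r_squared", "abs_r")),
              seed = as.integer(seed),
              version = as.character(utils::packageVersion("ntra")))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Reads per-subject pixel files and the covariate table, fits the trimodal
#' model and standard CT metrics per subject, discretizes each covariate,
#' runs the binned simple and multiple regressions, and writes all outputs
#' plus a machine-readable run manifest (configuration echo, per-stage
#' record counts, and an MD5 hash of every output file). Unreadable or
#' unfittable subjects are skipped with a warning; more than 10% failures
#' aborts the run.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `params`, `correlation` and `manifest`.
#'   Files written to `config$output_dir`: `ntra_parameters.csv`,
#'   `regressions.csv`, `selection.csv`, `bin_summary.csv`,
#'   `multiple_regression.json`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$pixel_dir)) stop("pixel directory does not exist")
  if (!file.exists(config$covariate_file)) stop("covariate file does not exist")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  files <- list.files(config$pixel_dir, pattern = "\\.(csv|txt)$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no pixel files found")
  covariates <- utils::read.csv(config$covariate_file,
                                stringsAsFactors = FALSE)

  pixel_sets <- list()
  unreadable <- character(0L)
  for (f in files) {
    ps <- tryCatch(
      read_pixel_csv(f, unit = config$unit, pixel_area = config$pixel_area),
      error = function(e) {
        warning(sprintf("skipping unreadable pixel file %s: %s", basename(f),
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(ps)) unreadable <- c(unreadable, basename(f))
    else pixel_sets[[ps$subject_id]] <- ps
  }

  message(sprintf("fitting %d subjects ...", length(pixel_sets)))
  params <- fit_cohort(pixel_sets, n_bins = config$n_bins,
                       hu_range = config$hu_range,
                       bandwidth = config$bandwidth,
                       normalize = config$normalize,
                       fat_threshold = config$fat_threshold,
                       n_restarts = config$n_restarts, tol = config$tol,
                       seed = config$seed)

  message("running binned correlation analysis ...")
  corr <- correlate_cohort(params, covariates, k = config$k,
                           threshold = config$threshold,
                           quantity = config$quantity,
                           method = config$method)

  out <- function(name) file.path(config$output_dir, name)
  utils::write.csv(params, out("ntra_parameters.csv"), row.names = FALSE)
  utils::write.csv(corr$regressions, out("regressions.csv"), row.names = FALSE)
  utils::write.csv(corr$selection$selected, out("selection.csv"),
                   row.names = FALSE)
  utils::write.csv(corr$bins, out("bin_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(corr$multiple, function(m) {
      list(coefficients = as.list(m$coefficients),
           multiple_r = m$multiple_r, r_squared = m$r_squared,
           f_statistic = m$f_statistic, p_value = m$p_value,
           df = as.list(m$df), anova = m$anova,
           dropped_collinear = m$dropped_collinear)
    }),
    out("multiple_regression.json"), auto_unbox = TRUE, digits = NA)

  outputs <- c("ntra_parameters.csv", "regressions.csv", "selection.csv",
               "bin_summary.csv", "multiple_regression.json")
  manifest <- list(
    config = unclass(config),
    counts = list(
      subjects_read = length(pixel_sets),
      subjects_fitted = nrow(params),
      subjects_unreadable = length(unreadable),
      subjects_failed_fit = length(attr(params, "failures")),
      covariates = length(unique(corr$regressions$covariate)),
      simple_regressions = corr$n_tests,
      selected = nrow(corr$selection$selected),
      per_covariate_n = as.list(stats::setNames(
        vapply(unique(corr$bins$covariate), function(cv)
          sum(corr$bins$n[corr$bins$covariate == cv]), numeric(1L)),
        unique(corr$bins$covariate)))
    ),
    files = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(out(f)))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(params = params, correlation = corr, manifest = manifest))
}
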
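#' Default covariate couplings of the synthetic cohort
#'
#' Each clinical covariate is an affine function of the latent health factor
#' `h` (0 = least healthy, 1 = healthiest) plus Gaussian noise:
#' `value = intercept + slope * h + N(0, noise_sd)`. Signs follow the
#' directions observed in aging cohorts: gait speeds and strength increase
#' with health, timed up-and-go, cholesterol and BMI decrease. Units: gait
#' speeds m/s, TUG s, strength N, cholesterol mmol/L, BMI kg/m^2.
#'
#' @return Data frame with columns `covariate`, `intercept`, `slope`,
#'   `noise_sd`.
#' @export
default_couplings <- function() {
  data.frame(
    covariate = c("gsn", "gsf", "tug", "str", "schol", "bmi"),
    intercept = c(0.7, 1.0, 14.0, 250, 6.4, 31.0),
    slope     = c(0.5, 0.7, -5.0, 150, -1.4, -6.0),
    noise_sd  = c(0.06, 0.08, 0.6, 18, 0.17, 0.7),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort specification
#'
#' Defines the generative model for a synthetic mid-thigh CT cohort: each
#' subject has a latent health factor drawn uniformly on \[0, 1\] that
#' linearly shifts the trimodal distribution parameters (muscle amplitude up,
#' fat amplitude down, connective location up with health) and, through the
#' couplings, the clinical covariates. Pixels are drawn from the subject's
#' trimodal mixture, giving exact ground truth for every downstream stage.
#'
#' @param n_subjects Number of subjects.
#' @param pixels_per_subject Pixels drawn per cross-section.
#' @param seed Integer seed; all cohort randomness flows from it.
#' @param base_params [ntra_params()] at `h = 0.5`, the cohort midpoint.
#' @param coupling Data frame as returned by [default_couplings()]; a slope
#'   of 0 decouples that covariate from health (a planted null).
#' @param age_range Uniform age range in years.
#' @param sex_ratio Probability a subject is male.
#' @param pixel_area Pixel area in mm^2.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000L, pixels_per_subject = 10000L,
                        seed = 1L, base_params = default_base_params(),
                        coupling = default_couplings(),
                        age_range = c(66, 96), sex_ratio = 0.42,
                        pixel_area = 1.0) {
  stopifnot(inherits(base_params, "ntra_params"))
  if (!is.data.frame(coupling) ||
      !all(c("covariate", "intercept", "slope", "noise_sd") %in% names(coupling))) {
    stop("`coupling` must have columns covariate, intercept, slope, noise_sd")
  }
  if (!all(is.finite(coupling$slope))) stop("coupling slopes must be finite")
  if (any(coupling$noise_sd < 0)) stop("coupling noise_sd must be >= 0")
  if (n_subjects < 1L || pixels_per_subject < 1L) {
    stop("`n_subjects` and `pixels_per_subject` must be positive")
  }
  if (sex_ratio <= 0 || sex_ratio >= 1) stop("`sex_ratio` must be in (0, 1)")
  # both extremes of the health factor must give valid, domain-ordered params
  health_shift_params(base_params, 0)
  health_shift_params(base_params, 1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         pixels_per_subject = as.integer(pixels_per_subject),
         seed = as.integer(seed), base_params = base_params,
         coupling = coupling, age_range = as.numeric(age_range),
         sex_ratio = sex_ratio, pixel_area = pixel_area),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_base_params <- function() {
  ntra_params(N = c(0.30, 0.15, 0.55), mu = c(-60, 10, 52),
              sigma = c(25, 12, 14), alpha = c(-2, 0, 1.5))
}

# Linear shift of the trimodal parameters with latent health h in [0, 1],
# centered at h = 0.5. Directions: healthier subjects have more muscle and
# less fat mass, a connective peak at higher HU, narrower fat and broader
# muscle peaks, less muscle skew and more negative fat skew.
health_shift_params <- function(base, h) {
  d <- h - 0.5
  ntra_params(
    N = c(base$N[[1L]] - 0.25 * d, base$N[[2L]] - 0.05 * d,
          base$N[[3L]] + 0.30 * d),
    mu = c(base$mu[[1L]], base$mu[[2L]] + 20 * d, base$mu[[3L]] + 4 * d),
    sigma = c(base$sigma[[1L]] - 8 * d, base$sigma[[2L]], base$sigma[[3L]] + 4 * d),
    alpha = c(base$alpha[[1L]] - 1.0 * d, 0, base$alpha[[3L]] - 1.2 * d)
  )
}

#' Sample pixels from one skewed-Gaussian component
#'
#' Draws from the skew-normal density proportional to
#' `exp(-(x-mu)^2/(2*sigma^2)) * erfc(alpha*(x-mu)/(sigma*sqrt(2)))`, i.e.
#' the normalized [component_density()], using the standard construction from
#' two correlated normals with skew-normal shape `-alpha` (the erfc
#' convention flips the sign relative to the usual shape parameter). The
#' sample mean converges to `mu - sigma * (alpha/sqrt(1+alpha^2)) * sqrt(2/pi)`.
#'
#' @param n Number of draws, positive.
#' @param mu,sigma,alpha Component location (HU), width (HU, positive) and
#'   skewness.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Numeric vector of `n` HU values.
#' @export
sample_component <- function(n, mu, sigma, alpha = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be a positive integer")
  if (sigma <= 0) stop("`sigma` must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  delta <- -alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  v <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * v
  mu + sigma * z
}

#' Generate one synthetic subject
#'
#' Derives the subject's true trimodal parameters from the latent health
#' factor, then draws pixels from the mixture with component probabilities
#' proportional to the amplitudes.
#'
#' @param latent_health Health factor in \[0, 1\].
#' @param spec A [cohort_spec()].
#' @param subject_id Identifier for the returned pixel set.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list with `pixels` (a [pixel_set()] in HU) and `params` (the
#'   true [ntra_params()]).
#' @export
generate_subject <- function(latent_health, spec, subject_id = "s1",
                             seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (latent_health < 0 || latent_health > 1) stop("`latent_health` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  params <- health_shift_params(spec$base_params, latent_health)

  n <- spec$pixels_per_subject
  probs <- params$N / sum(params$N)
  counts <- as.integer(stats::rmultinom(1L, n, probs))
  vals <- numeric(0L)
  for (i in 1:3) {
    if (counts[[i]] > 0L) {
      vals <- c(vals, sample_component(counts[[i]], params$mu[[i]],
                                       params$sigma[[i]], params$alpha[[i]]))
    }
  }
  list(pixels = pixel_set(vals, subject_id = subject_id,
                          unit = "hounsfield", pixel_area = spec$pixel_area),
       params = params)
}

#' Generate a full synthetic cohort
#'
#' Draws latent health factors, per-subject pixel sets and the clinical
#' covariate table (gait speeds, timed up-and-go, strength, cholesterol,
#' BMI — affine in health plus noise — and age/sex, which are independent of
#' health). Fully deterministic for a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `pixels` (named list of
#'   [pixel_set()]s), `covariates` (data frame: subject_id, age, sex, then
#'   one column per coupled covariate), `truth` (data frame of latent health
#'   and the true trimodal parameters per subject), and `spec`.
#' @seealso [write_cohort()] to materialize the pipeline's input files.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ids <- sprintf("s%04d", seq_len(n))
  h <- stats::runif(n)
  age <- stats::runif(n, spec$age_range[[1L]], spec$age_range[[2L]])
  sex <- ifelse(stats::rbinom(n, 1L, spec$sex_ratio) == 1L, "M", "F")

  cov <- data.frame(subject_id = ids, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(spec$coupling))) {
    cp <- spec$coupling[r, ]
    cov[[cp$covariate]] <- cp$intercept + cp$slope * h +
      stats::rnorm(n, sd = cp$noise_sd)
  }

  pixels <- vector("list", n)
  names(pixels) <- ids
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- generate_subject(h[[i]], spec, subject_id = ids[[i]])
    pixels[[i]] <- subj$pixels
    p <- ntra_flatten(subj$params)
    truth[[i]] <- data.frame(subject_id = ids[[i]], latent_health = h[[i]],
                             t(p), stringsAsFactors = FALSE)
  }

  structure(
    list(pixels = pixels, covariates = cov,
         truth = do.call(rbind, truth), spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %d pixels, seed %d\n",
              x$spec$n_subjects, x$spec$pixels_per_subject, x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Materializes the file formats consumed by [run_pipeline()]: one
#' single-column pixel CSV per subject under `dir/pixels/`, a covariate
#' table `covariates.csv`, and the ground-truth parameter table `truth.csv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  px_dir <- file.path(dir, "pixels")
  dir.create(px_dir, recursive = TRUE, showWarnings = FALSE)
  for (ps in cohort$pixels) {
    utils::write.csv(data.frame(hu = ps$values),
                     file.path(px_dir, paste0(ps$subject_id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
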
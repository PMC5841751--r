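# complementary error function via the normal CDF
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Trimodal model parameters
#'
#' The 11-parameter state of the trimodal radiodensity model: three
#' components, indexed fat (1), loose connective / water-equivalent tissue
#' (2) and muscle (3), each with an amplitude `N` (probability mass of the
#' component), location `mu` (HU), width `sigma` (HU) and skewness `alpha`.
#' The central connective component is a standard Gaussian, so `alpha[2]` is
#' structurally fixed at 0 and the model has 3 + 3 + 3 + 2 = 11 free entries.
#'
#' @param N Three non-negative amplitudes.
#' @param mu Three strictly increasing locations, HU.
#' @param sigma Three positive widths, HU.
#' @param alpha Three skewnesses; `alpha[2]` must be 0.
#' @return An object of class `ntra_params`.
#' @examples
#' p <- ntra_params(N = c(0.3, 0.15, 0.55), mu = c(-60, 10, 52),
#'                  sigma = c(25, 12, 14), alpha = c(-2, 0, 1.5))
#' n_free_parameters(p)
#' @export
ntra_params <- function(N, mu, sigma, alpha = c(0, 0, 0)) {
  if (length(N) != 3L || length(mu) != 3L || length(sigma) != 3L ||
      length(alpha) != 3L) {
    stop("N, mu, sigma and alpha must each have length 3")
  }
  vals <- c(N, mu, sigma, alpha)
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    stop("all parameters must be finite numbers")
  }
  if (any(N < 0)) stop("amplitudes N must be non-negative")
  if (any(sigma <= 0)) stop("widths sigma must be positive")
  if (!(mu[[1L]] < mu[[2L]] && mu[[2L]] < mu[[3L]])) {
    stop("locations must be ordered: mu[1] < mu[2] < mu[3]")
  }
  if (alpha[[2L]] != 0) {
    stop("the central (connective tissue) component is unskewed: alpha[2] must be 0")
  }
  structure(list(N = as.numeric(N), mu = as.numeric(mu),
                 sigma = as.numeric(sigma), alpha = as.numeric(alpha)),
            class = "ntra_params")
}

#' @export
print.ntra_params <- function(x, ...) {
  m <- rbind(N = x$N, mu = x$mu, sigma = x$sigma, alpha = x$alpha)
  colnames(m) <- c("fat", "connective", "muscle")
  cat("<ntra_params> (11 free parameters, alpha[2] fixed at 0)\n")
  print(round(m, 4))
  invisible(x)
}

#' Number of free parameters of the trimodal model
#'
#' Counts the entries of an [ntra_params()] object that are free to vary in
#' fitting: all amplitudes, locations and widths plus the fat and muscle
#' skewnesses (`alpha[2]` is structurally 0).
#'
#' @param params An `ntra_params` object.
#' @return Integer, always 11 for a valid object.
#' @export
n_free_parameters <- function(params) {
  stopifnot(inherits(params, "ntra_params"))
  fixed_alpha2 <- 1L # alpha[2] == 0 enforced by the constructor
  length(params$N) + length(params$mu) + length(params$sigma) +
    length(params$alpha) - fixed_alpha2
}

#' Flatten / restore the free-parameter vector
#'
#' Order: N1..N3, mu1..mu3, sigma1..sigma3, alpha1, alpha3.
#' @param params An `ntra_params` object.
#' @return `ntra_flatten` gives a named length-11 numeric vector;
#'   `ntra_unflatten` rebuilds the `ntra_params` object.
#' @keywords internal
#' @export
ntra_flatten <- function(params) {
  stopifnot(inherits(params, "ntra_params"))
  stats::setNames(
    c(params$N, params$mu, params$sigma, params$alpha[c(1L, 3L)]),
    c("N1", "N2", "N3", "mu1", "mu2", "mu3",
      "sigma1", "sigma2", "sigma3", "alpha1", "alpha3"))
}

#' @rdname ntra_flatten
#' @param p Length-11 numeric vector in `ntra_flatten` order.
#' @export
ntra_unflatten <- function(p) {
  stopifnot(is.numeric(p), length(p) == 11L)
  ntra_params(N = p[1:3], mu = p[4:6], sigma = p[7:9],
              alpha = c(p[[10L]], 0, p[[11L]]))
}

#' Single skewed-Gaussian component density
#'
#' Evaluates one component of the trimodal model,
#' `N/(sigma*sqrt(2*pi)) * exp(-(x-mu)^2/(2*sigma^2)) *
#'  erfc(alpha*(x-mu)/(sigma*sqrt(2)))`.
#' This is `N` times a skew-normal density; its integral over the real line
#' is the amplitude `N` (the odd error-function term integrates to zero), so
#' the trimodal sum is a quasi-probability density whose component masses are
#' the amplitudes. Note the erfc convention: positive `alpha` skews the
#' component to the left.
#'
#' @param x Numeric vector of HU values.
#' @param N Amplitude (component mass), non-negative.
#' @param mu Location, HU.
#' @param sigma Width, HU, positive.
#' @param alpha Skewness (0 gives `N` times a Gaussian density).
#' @return Non-negative density values, one per element of `x`.
#' @export
component_density <- function(x, N, mu, sigma, alpha = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  z <- (x - mu) / sigma
  (N / (sigma * sqrt(2 * pi))) * exp(-z^2 / 2) * erfc(alpha * z / sqrt(2))
}

#' Trimodal quasi-density
#'
#' Pointwise sum of the three component densities of an [ntra_params()]
#' state. Its integral over the real line is `sum(N)`.
#'
#' @param x Numeric vector of HU values.
#' @param params An `ntra_params` object.
#' @return Numeric vector of density values.
#' @export
trimodal_density <- function(x, params) {
  stopifnot(inherits(params, "ntra_params"))
  out <- numeric(length(x))
  for (i in 1:3) {
    out <- out + component_density(x, params$N[[i]], params$mu[[i]],
                                   params$sigma[[i]], params$alpha[[i]])
  }
  out
}

#' Soft-tissue HU domains
#'
#' The disjoint, ascending HU intervals occupied by the three soft-tissue
#' types on the Hounsfield scale: fat \[-200, -10\], loose connective /
#' water-equivalent tissue \[-9, 40\], muscle \[41, 200\]. The domains anchor
#' model initialization and constrain each component's location during
#' fitting, which fixes the component labelling.
#'
#' @param fat,connective,muscle Length-2 ascending HU intervals.
#' @return An object of class `tissue_domains` (list of three intervals).
#' @export
tissue_domains <- function(fat = c(-200, -10), connective = c(-9, 40),
                           muscle = c(41, 200)) {
  doms <- list(fat = as.numeric(fat), connective = as.numeric(connective),
               muscle = as.numeric(muscle))
  for (nm in names(doms)) {
    d <- doms[[nm]]
    if (length(d) != 2L || !all(is.finite(d)) || d[[1L]] >= d[[2L]]) {
      stop(sprintf("domain `%s` must be an ascending finite interval", nm))
    }
  }
  if (!(doms$fat[[2L]] < doms$connective[[1L]] &&
        doms$connective[[2L]] < doms$muscle[[1L]])) {
    stop("domains must be disjoint and ascending: fat < connective < muscle")
  }
  structure(doms, class = "tissue_domains")
}

#' Domain-based initialization of the trimodal model
#'
#' Builds starting values for [fit_ntra()] from the smoothed density: per
#' tissue domain, the amplitude starts at the density mass inside the domain,
#' the location at the domain's density centroid, the width at the domain's
#' density standard deviation (floored at one bin width), and the skewness at
#' zero. A domain with no mass gets a small positive amplitude floor and its
#' midpoint as location, so degenerate inputs initialize rather than fail.
#'
#' @param hist A smoothed `hu_histogram` (see [smooth_histogram()]).
#' @param domains A [tissue_domains()] object.
#' @return An [ntra_params()] object.
#' @export
initialize_from_domains <- function(hist, domains = tissue_domains()) {
  stopifnot(inherits(hist, "hu_histogram"))
  if (is.null(hist$density)) stop("histogram density not populated; run smooth_histogram() first")
  x <- hist$bin_centers
  d <- hist$density
  bw <- hist$bin_width

  N0 <- mu0 <- s0 <- numeric(3L)
  for (i in 1:3) {
    dom <- domains[[i]]
    sel <- x >= dom[[1L]] & x <= dom[[2L]]
    mass <- sum(d[sel]) * bw
    if (mass <= 0) {
      N0[[i]] <- 1e-6
      mu0[[i]] <- mean(dom)
      s0[[i]] <- max(bw, diff(dom) / 6)
    } else {
      w <- d[sel] / sum(d[sel])
      N0[[i]] <- mass
      mu0[[i]] <- sum(w * x[sel])
      s0[[i]] <- max(bw, sqrt(sum(w * (x[sel] - mu0[[i]])^2)))
    }
  }
  # centroids of adjacent domains can only tie in degenerate cases; nudge
  # inside the domain to satisfy the strict ordering invariant
  eps <- 1e-9
  for (i in 2:3) if (mu0[[i]] <= mu0[[i - 1L]]) mu0[[i]] <- mu0[[i - 1L]] + eps
  ntra_params(N = N0, mu = mu0, sigma = s0, alpha = c(0, 0, 0))
}

default_fit_bounds <- function(hist, domains) {
  bw <- hist$bin_width
  total_mass <- sum(hist$density) * bw
  list(
    lower = c(N1 = 0, N2 = 0, N3 = 0,
              mu1 = domains$fat[[1L]], mu2 = domains$connective[[1L]],
              mu3 = domains$muscle[[1L]],
              sigma1 = bw, sigma2 = bw, sigma3 = bw,
              alpha1 = -20, alpha3 = -20),
    upper = c(N1 = total_mass, N2 = total_mass, N3 = total_mass,
              mu1 = domains$fat[[2L]], mu2 = domains$connective[[2L]],
              mu3 = domains$muscle[[2L]],
              sigma1 = 100, sigma2 = 100, sigma3 = 100,
              alpha1 = 20, alpha3 = 20)
  )
}

#' Fit the trimodal model to a smoothed HU histogram
#'
#' Estimates the 11 free parameters by bound-constrained nonlinear least
#' squares on the smoothed density at the bin centers (Levenberg-Marquardt
#' via [minpack.lm::nls.lm()]), i.e. minimizing the sum of squared residuals
#' between the empirical density curve and [trimodal_density()]. Each
#' component's location is confined to its tissue domain, which enforces the
#' fat < connective < muscle ordering and prevents label switching;
#' `alpha[2]` is held at 0 throughout. The optimizer is restarted from
#' jittered initializations and the best solution kept.
#'
#' @param hist A smoothed `hu_histogram` with at least 32 bins.
#' @param init Starting [ntra_params()], or `"auto"` for
#'   [initialize_from_domains()].
#' @param domains A [tissue_domains()] object (location bounds).
#' @param bounds Optional list with `lower` and `upper` length-11 vectors in
#'   [ntra_flatten()] order, overriding the defaults (`N` in \[0, total
#'   mass\], `mu` in its domain, `sigma` in \[bin width, 100\] HU, `alpha` in
#'   \[-20, 20\]).
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap per start (the optimizer itself caps at 1024).
#' @param n_restarts Number of jittered restarts in addition to the initial
#'   start; 0 fits once from `init`.
#' @param seed Seed for the restart jitter; `NULL` uses the current RNG state.
#' @return An object of class `ntra_fit`: `params` (the best
#'   [ntra_params()]), `r_squared` (1 - SSE over the total sum of squares of
#'   the target curve), `sse`, `n_iterations`, `converged`, and `restart_sse`
#'   (best-so-far SSE after each start, non-increasing).
#' @export
fit_ntra <- function(hist, init = "auto", domains = tissue_domains(),
                     bounds = NULL, tol = 1e-10, max_iter = 5000L,
                     n_restarts = 4L, seed = NULL) {
  stopifnot(inherits(hist, "hu_histogram"))
  if (is.null(hist$density)) stop("histogram density not populated; run smooth_histogram() first")
  x <- hist$bin_centers
  y <- hist$density
  if (length(y) < 32L) stop("at least 32 bins are required for a stable fit")
  if (all(y == 0)) stop("density is identically zero: no mass to fit")

  if (identical(init, "auto")) init <- initialize_from_domains(hist, domains)
  stopifnot(inherits(init, "ntra_params"))

  b <- if (is.null(bounds)) default_fit_bounds(hist, domains) else bounds
  if (!is.list(b) || length(b$lower) != 11L || length(b$upper) != 11L ||
      any(b$lower > b$upper)) {
    stop("`bounds` must be a list with length-11 `lower` <= `upper` vectors")
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  residual_fn <- function(p) y - trimodal_density(x, ntra_unflatten(p))
  clip <- function(p) pmin(pmax(p, b$lower), b$upper)
  p0 <- clip(ntra_flatten(init))

  jitter_start <- function(p) {
    q <- p
    q[1:3] <- q[1:3] * exp(stats::rnorm(3L, sd = 0.2))
    dom_w <- vapply(domains, diff, numeric(1L))
    q[4:6] <- q[4:6] + stats::rnorm(3L, sd = 0.1 * dom_w)
    q[7:9] <- q[7:9] * exp(stats::rnorm(3L, sd = 0.25))
    q[10:11] <- q[10:11] + stats::rnorm(2L, sd = 1)
    clip(q)
  }

  ctrl <- minpack.lm::nls.lm.control(
    maxiter = min(as.integer(max_iter), 1024L),
    ftol = tol, ptol = tol, maxfev = 100000L)

  best <- NULL
  restart_sse <- numeric(0L)
  for (r in 0:max(0L, as.integer(n_restarts))) {
    start <- if (r == 0L) p0 else jitter_start(p0)
    # nls.lm warns when maxiter is hit; the converged flag reports that
    res <- suppressWarnings(
      minpack.lm::nls.lm(par = start, lower = b$lower, upper = b$upper,
                         fn = residual_fn, control = ctrl))
    sse <- res$deviance
    if (is.null(best) || sse < best$deviance) best <- res
    restart_sse <- c(restart_sse, if (is.null(best)) sse else best$deviance)
  }

  tss <- sum((y - mean(y))^2)
  structure(
    list(
      params = ntra_unflatten(clip(best$par)),
      r_squared = max(0, min(1, 1 - best$deviance / tss)),
      sse = best$deviance,
      n_iterations = best$niter,
      converged = best$info %in% 1:4,
      restart_sse = restart_sse
    ),
    class = "ntra_fit"
  )
}

#' @export
print.ntra_fit <- function(x, ...) {
  cat(sprintf("<ntra_fit> R^2 = %.6f, SSE = %.3e, %d iterations, %s\n",
              x$r_squared, x$sse, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}
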
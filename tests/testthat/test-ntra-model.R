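test_that("unskewed component is the scaled Gaussian density", {
  expect_equal(component_density(0, N = 1, mu = 0, sigma = 1, alpha = 0),
               1 / sqrt(2 * pi))
  set.seed(11)
  x <- stats::rnorm(20, sd = 50)
  expect_equal(component_density(x, N = 2.5, mu = 10, sigma = 14, alpha = 0),
               2.5 * stats::dnorm(x, 10, 14), tolerance = 1e-12)
})

test_that("component mass equals the amplitude for random parameters", {
  set.seed(22)
  for (i in 1:100) {
    N <- stats::runif(1, 0.1, 2)
    mu <- stats::runif(1, -100, 100)
    sigma <- stats::runif(1, 2, 40)
    alpha <- stats::runif(1, -5, 5)
    mass <- component_mass_quadrature(N, mu, sigma, alpha)
    expect_lt(abs(mass - N) / N, 1e-6)
  }
})

test_that("component density is non-negative and rejects bad width", {
  x <- seq(-200, 200, length.out = 401)
  expect_true(all(component_density(x, 1, -60, 25, -3) >= 0))
  expect_true(all(component_density(x, 1, 52, 14, 4) >= 0))
  expect_error(component_density(0, 1, 0, 0, 0), "positive")
  expect_error(component_density(0, 1, 0, -1, 0), "positive")
})

test_that("trimodal density is the sum of its components", {
  p <- test_params()
  x <- seq(-200, 200, length.out = 201)
  manual <- component_density(x, p$N[1], p$mu[1], p$sigma[1], p$alpha[1]) +
    component_density(x, p$N[2], p$mu[2], p$sigma[2], p$alpha[2]) +
    component_density(x, p$N[3], p$mu[3], p$sigma[3], p$alpha[3])
  expect_equal(trimodal_density(x, p), manual)

  # zeroing two components leaves the survivor
  p2 <- ntra_params(N = c(0, 0, 0.55), mu = p$mu, sigma = p$sigma,
                    alpha = p$alpha)
  expect_equal(trimodal_density(x, p2),
               component_density(x, 0.55, p$mu[3], p$sigma[3], p$alpha[3]))

  p0 <- ntra_params(N = c(0, 0, 0), mu = p$mu, sigma = p$sigma,
                    alpha = p$alpha)
  expect_equal(trimodal_density(x, p0), numeric(201))

  total <- sum(vapply(1:3, function(i)
    component_mass_quadrature(p$N[i], p$mu[i], p$sigma[i], p$alpha[i]),
    numeric(1)))
  expect_lt(abs(total - sum(p$N)), 1e-6)
})

test_that("parameter container enforces the structural invariants", {
  p <- test_params()
  expect_identical(n_free_parameters(p), 11L)
  expect_identical(p$alpha[[2]], 0)
  expect_error(ntra_params(c(1, 1, 1), c(-60, 10, 52), c(1, 1, 1),
                           alpha = c(0, 0.5, 0)), "alpha\\[2\\]")
  expect_error(ntra_params(c(1, 1, 1), c(10, -60, 52), c(1, 1, 1)),
               "ordered")
  expect_error(ntra_params(c(-1, 1, 1), c(-60, 10, 52), c(1, 1, 1)),
               "non-negative")
  expect_equal(ntra_unflatten(ntra_flatten(p)), p)
})

test_that("domain initialization locates well-separated narrow peaks", {
  p <- ntra_params(N = c(0.3, 0.2, 0.5), mu = c(-80, 15, 60),
                   sigma = c(10, 6, 8), alpha = c(0, 0, 0))
  h <- sampled_histogram(p, 1e5, seed = 33)
  init <- initialize_from_domains(h)
  expect_true(all(abs(init$mu - p$mu) <= 2))
  expect_true(all(init$sigma > 0))
})

test_that("domain initialization handles uniform and empty-domain densities", {
  # exactly uniform density: centroids at the domain midpoints (up to bin
  # alignment at the domain edges)
  centers <- -200 + 3.125 * (1:128 - 0.5)
  h <- build_histogram(pixel_set(rep(centers, each = 10)))
  h <- smooth_histogram(h, bandwidth = 1e-6) # keep the density flat
  init <- initialize_from_domains(h)
  doms <- tissue_domains()
  for (i in 1:3) {
    expect_lt(abs(init$mu[[i]] - mean(doms[[i]])), h$bin_width)
  }

  # no mass in the muscle domain: floored amplitude, midpoint location
  x <- c(stats::rnorm(5000, -60, 20), stats::rnorm(2000, 10, 8))
  h2 <- smooth_histogram(build_histogram(pixel_set(pmin(x, 38)),
                                         hu_range = c(-200, 200)),
                         bandwidth = 1e-6)
  init2 <- initialize_from_domains(h2)
  expect_equal(init2$N[[3]], 1e-6)
  expect_equal(init2$mu[[3]], mean(c(41, 200)))
})

test_that("fit recovers exactly trimodal target curves to high precision", {
  p <- test_params()
  h <- build_histogram(pixel_set(rep(0, 100))) # carrier for the grid
  h$density <- trimodal_density(h$bin_centers, p)
  fit <- fit_ntra(h, n_restarts = 0)
  expect_true(fit$converged)
  expect_gte(fit$r_squared, 1 - 1e-8)
  truth <- ntra_flatten(p)
  est <- ntra_flatten(fit$params)
  expect_true(all(abs(est - truth) / pmax(abs(truth), 1e-8) < 1e-3))
})

test_that("fit recovers parameters from sampled pixels", {
  p <- test_params()
  h <- sampled_histogram(p, 1e5, seed = 44)
  fit <- fit_ntra(h, n_restarts = 4, seed = 55)
  expect_true(fit$converged)
  expect_true(all(abs(fit$params$mu - p$mu) <= 2))
  expect_true(all(abs(fit$params$N - p$N) / p$N <= 0.05))
})

test_that("refitting from a converged solution is idempotent", {
  p <- test_params()
  h <- sampled_histogram(p, 2e4, seed = 66)
  fit1 <- fit_ntra(h, n_restarts = 2, seed = 77)
  fit2 <- fit_ntra(h, init = fit1$params, n_restarts = 0)
  expect_lt(abs(fit2$sse - fit1$sse) / fit1$sse, 1e-10)
})

test_that("best-of-restarts objective is non-increasing in restart count", {
  p <- test_params()
  h <- sampled_histogram(p, 2e4, seed = 88)
  fit <- fit_ntra(h, n_restarts = 6, seed = 99)
  expect_true(all(diff(fit$restart_sse) <= 0))
})

test_that("fit rejects massless and malformed inputs", {
  h <- build_histogram(pixel_set(rep(0, 10)))
  h$density <- rep(0, 128)
  expect_error(fit_ntra(h), "no mass")
  h2 <- build_histogram(pixel_set(rep(0, 10)))
  expect_error(fit_ntra(h2), "density not populated")
  h2 <- smooth_histogram(h2)
  expect_error(fit_ntra(h2, bounds = list(lower = rep(0, 3), upper = rep(1, 3))),
               "length-11")
})

test_that("sampled component mean follows the skew-normal mean law", {
  set.seed(111)
  for (alpha in c(-3, 0, 1.5)) {
    x <- sample_component(1e6, mu = 20, sigma = 15, alpha = alpha)
    mc_se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - skew_component_mean(20, 15, alpha)), 4 * mc_se)
    if (alpha == 0) expect_equal(stats::sd(x), 15, tolerance = 5e-3)
  }
})
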
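# Independent oracles used across the suite.

# Exhaustive search over all contiguous partitions of sorted values into k
# segments; returns the minimal within-cluster sum of squares. Feasible for
# n <= 12 (search space C(n-1, k-1)).
brute_force_1d_sse <- function(values, k) {
  xs <- sort(values)
  n <- length(xs)
  seg_sse <- function(a, b) sum((xs[a:b] - mean(xs[a:b]))^2)
  if (k == 1L) return(seg_sse(1L, n))
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, j], n)
    sse <- sum(vapply(seq_len(k), function(i)
      seg_sse(bounds[[i]] + 1L, bounds[[i + 1L]]), numeric(1L)))
    best <- min(best, sse)
  }
  best
}

# Quadrature mass of one skewed component over an interval wide enough to
# capture all mass (the tails are sub-Gaussian on one side, Gaussian on the
# other).
component_mass_quadrature <- function(N, mu, sigma, alpha) {
  stats::integrate(function(x) component_density(x, N, mu, sigma, alpha),
                   lower = mu - 60 * sigma, upper = mu + 60 * sigma,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 2000L)$value
}

# Mean of the skew-normal under the erfc sign convention used by the model.
skew_component_mean <- function(mu, sigma, alpha) {
  mu - sigma * (alpha / sqrt(1 + alpha^2)) * sqrt(2 / pi)
}

# Small trimodal test cohort parameters (well separated peaks).
test_params <- function() {
  ntra_params(N = c(0.3, 0.15, 0.55), mu = c(-60, 10, 52),
              sigma = c(25, 12, 14), alpha = c(-2, 0, 1.5))
}

# Histogram of pixels sampled from given trimodal parameters.
sampled_histogram <- function(params, n_pixels, seed, bandwidth = "auto") {
  set.seed(seed)
  probs <- params$N / sum(params$N)
  counts <- as.integer(stats::rmultinom(1L, n_pixels, probs))
  vals <- unlist(lapply(1:3, function(i)
    sample_component(counts[[i]], params$mu[[i]], params$sigma[[i]],
                     params$alpha[[i]])))
  smooth_histogram(build_histogram(pixel_set(vals)), bandwidth = bandwidth)
}
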
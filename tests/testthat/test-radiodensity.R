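test_that("CT-number calibration evaluates and inverts correctly", {
  expect_equal(ct_to_hu(0), -190)
  expect_equal(ct_to_hu(100), 36.625)
  root <- 190 / 2.26625
  expect_lt(abs(ct_to_hu(root)), 1e-9)
  expect_equal(ct_to_hu(c(1, 2, 3)), c(1, 2, 3) * 2.26625 - 190)
})

test_that("CT-number calibration is affine and rejects non-finite input", {
  set.seed(101)
  for (i in 1:20) {
    a <- stats::rnorm(1); b <- stats::rnorm(1); v <- stats::rnorm(5)
    expect_equal(ct_to_hu(a * v + b), a * 2.26625 * v + (2.26625 * b - 190))
  }
  expect_error(ct_to_hu(c(1, NaN, 3)), "index 2")
  expect_error(ct_to_hu(c(Inf, 1)), "index 1")
})

test_that("unit flag applies the calibration exactly once", {
  raw <- pixel_set(c(0, 100), unit = "ct_number")
  hu <- as_hu(raw)
  expect_equal(hu$values, c(-190, 36.625))
  expect_identical(as_hu(hu)$values, hu$values) # no double transform
})

test_that("histogram bins a point mass into a single bin", {
  h <- build_histogram(pixel_set(rep(0, 1000)))
  expect_equal(length(h$counts), 128L)
  expect_equal(sum(h$counts), 1000)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$counts[[which(h$counts > 0)]], 1000)
  expect_true(all(diff(h$bin_edges) > 0))
  expect_equal(diff(h$bin_edges), rep(h$bin_width, 128L))
})

test_that("histogram reports out-of-range pixels instead of dropping them", {
  h <- build_histogram(pixel_set(c(-250, 0, 250)))
  expect_equal(sum(h$counts), 1)
  expect_equal(h$n_out_of_range, 2L)
  expect_equal(h$total_pixels, 3L)
})

test_that("histogram mass is conserved for random inputs", {
  set.seed(202)
  for (i in 1:10) {
    x <- stats::rnorm(500, sd = 150)
    h <- build_histogram(pixel_set(x))
    expect_equal(sum(h$counts) + h$n_out_of_range, length(x))
  }
})

test_that("uniform samples give per-bin counts within 5 sigma of n/128", {
  set.seed(303)
  n <- 2e5
  h <- build_histogram(pixel_set(stats::runif(n, -200, 200)))
  p <- 1 / 128
  expect_true(all(abs(h$counts - n * p) <= 5 * sqrt(n * p * (1 - p))))
})

test_that("histogram rejects degenerate inputs", {
  expect_error(build_histogram(pixel_set(1), hu_range = c(200, -200)),
               "inverted")
  expect_error(build_histogram(pixel_set(1), n_bins = 4), ">= 8")
  expect_error(pixel_set(numeric(0)), "non-empty")
})

test_that("smoothing conserves unit integral on a trimodal sample", {
  h <- sampled_histogram(test_params(), 1e5, seed = 404)
  trap <- sum((h$density[-1] + h$density[-128]) / 2) * h$bin_width
  expect_lt(abs(trap - 1), 1e-3)
  expect_true(all(h$density >= 0))
})

test_that("smoothing conserves integral for random histograms in both modes", {
  set.seed(505)
  for (i in 1:5) {
    x <- stats::rnorm(2000, mean = stats::runif(1, -50, 50), sd = 30)
    h <- build_histogram(pixel_set(x))
    hd <- smooth_histogram(h, normalize = "density")
    expect_equal(sum(hd$density) * hd$bin_width, 1, tolerance = 1e-10)
    hc <- smooth_histogram(h, normalize = "counts")
    expect_equal(sum(hc$density) * hc$bin_width, sum(h$counts),
                 tolerance = 1e-10)
  }
})

test_that("an impulse smooths to the kernel centred on its bin", {
  x <- rep(0, 1000) # single nonzero bin
  h <- build_histogram(pixel_set(x))
  bwidth <- 5
  hs <- smooth_histogram(h, bandwidth = bwidth)
  j <- which(h$counts > 0)
  kern <- exp(-(h$bin_centers - h$bin_centers[[j]])^2 / (2 * bwidth^2))
  kern <- kern / sum(kern) / h$bin_width
  expect_equal(hs$density, kern, tolerance = 1e-12)
})

test_that("vanishing bandwidth recovers normalized counts per bin width", {
  set.seed(606)
  h <- build_histogram(pixel_set(stats::rnorm(5000, sd = 60)))
  hs <- smooth_histogram(h, bandwidth = 1e-6)
  expect_equal(hs$density, h$counts / sum(h$counts) / h$bin_width,
               tolerance = 1e-12)
})

test_that("smoothing rejects non-positive bandwidth", {
  h <- build_histogram(pixel_set(rep(0, 10)))
  expect_error(smooth_histogram(h, bandwidth = 0), "positive")
  expect_error(smooth_histogram(h, bandwidth = -2), "positive")
})

test_that("pixel CSV round-trip preserves values and subject id", {
  dir <- withr::local_tempdir()
  ps <- pixel_set(c(-12.5, 0, 42.25), subject_id = "s0001")
  utils::write.csv(data.frame(hu = ps$values),
                   file.path(dir, "s0001.csv"), row.names = FALSE)
  back <- read_pixel_csv(file.path(dir, "s0001.csv"))
  expect_equal(back$values, ps$values)
  expect_equal(back$subject_id, "s0001")
})
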
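make_table <- function(n, f) {
  data.frame(subject_id = sprintf("s%03d", 1:n), par = f, stringsAsFactors = FALSE)
}

test_that("bin aggregation preserves constant and identity couplings", {
  set.seed(13)
  x <- stats::rnorm(120)
  asg <- kmeans_1d(x, 6)

  const <- aggregate_bins(asg, x, make_table(120, rep(3.5, 120)), "cov")
  expect_equal(const$par$y, rep(3.5, 6))
  expect_equal(const$par$covariate_name, "cov")

  ident <- aggregate_bins(asg, x, make_table(120, x), "cov")
  expect_equal(ident$par$x, ident$par$y)
  expect_true(all(diff(ident$par$x) > 0))
  expect_equal(sum(ident$par$bin_n), 120L)
})

test_that("bin means track a planted linear coupling within standard error", {
  set.seed(24)
  n <- 1200
  x <- stats::runif(n)
  noise_sd <- 0.3
  y <- 2 + 5 * x + stats::rnorm(n, sd = noise_sd)
  asg <- kmeans_1d(x, 12)
  s <- aggregate_bins(asg, x, make_table(n, y), "cov")$par
  se <- noise_sd / sqrt(s$bin_n)
  expect_true(all(abs(s$y - (2 + 5 * s$x)) <= 4 * se))
})

test_that("subjects with missing values are dropped and counted", {
  set.seed(35)
  x <- stats::rnorm(60)
  pars <- make_table(60, stats::rnorm(60))
  pars$par[c(3, 7)] <- NA
  asg <- kmeans_1d(x, 3)
  s <- aggregate_bins(asg, x, pars, "cov")$par
  expect_equal(s$n_dropped, 2L)
  expect_equal(sum(s$bin_n), 58L)
})

test_that("simple fit reproduces exact lines and null fits", {
  x <- seq(1, 12)
  exact <- linear_fit(list(x = x, y = 2 * x + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- linear_fit(list(x = x, y = rep(4, 12)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(linear_fit(list(x = rep(1, 12), y = x)), "zero variance")
  expect_error(linear_fit(list(x = 1:2, y = 1:2)), "at least 3")
})

test_that("simple fit equals the closed-form normal-equation solution", {
  set.seed(46)
  for (i in 1:10) {
    x <- stats::rnorm(12)
    y <- stats::rnorm(12)
    fit <- linear_fit(list(x = x, y = y))
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("r_squared is invariant under affine rescaling of both axes", {
  set.seed(57)
  x <- stats::rnorm(12)
  y <- 3 * x + stats::rnorm(12, sd = 0.5)
  base <- linear_fit(list(x = x, y = y))$r_squared
  resc <- linear_fit(list(x = 100 * x - 7, y = -0.01 * y + 3))$r_squared
  expect_equal(resc, base, tolerance = 1e-12)
})

test_that("high-fidelity selection applies the >= 0.85 boundary rule", {
  res <- data.frame(
    covariate = "gsn", parameter = c("a", "b", "c"),
    r_squared = c(0.84, 0.85, 0.86), stringsAsFactors = FALSE)
  sel <- select_high_fidelity(res)
  expect_setequal(sel$selected$parameter, c("b", "c"))
  expect_equal(unname(sel$incidence[, "gsn"]), c(FALSE, TRUE, TRUE))

  all_in <- select_high_fidelity(transform(res, r_squared = 1))
  expect_equal(nrow(all_in$selected), 3L)
  none <- select_high_fidelity(transform(res, r_squared = 0))
  expect_equal(nrow(none$selected), 0L)

  # |R| variant: r^2 = 0.75 has |r| ~ 0.866 >= 0.85
  byr <- select_high_fidelity(transform(res, r_squared = 0.75),
                              quantity = "abs_r")
  expect_equal(nrow(byr$selected), 3L)
})

test_that("multiple regression reduces, saturates and tests as expected", {
  set.seed(68)
  k <- 12
  X <- matrix(stats::rnorm(k * 2), ncol = 2, dimnames = list(NULL, c("p1", "p2")))

  # exact linear combination is fully explained
  y <- 1 + 2 * X[, 1] - 3 * X[, 2]
  m <- multiple_fit(y, X)
  expect_equal(m$multiple_r, 1, tolerance = 1e-7)
  expect_equal(unname(m$coefficients), c(1, 2, -3), tolerance = 1e-8)

  # single predictor reduces to the simple fit
  y2 <- 2 * X[, 1] + stats::rnorm(k, sd = 0.4)
  m1 <- multiple_fit(y2, X[, 1, drop = FALSE])
  expect_equal(m1$multiple_r, abs(stats::cor(y2, X[, 1])), tolerance = 1e-10)
  expect_equal(m1$df, c(numerator = 1, denominator = k - 2))

  # planted model with small noise is overwhelmingly significant
  expect_lt(multiple_fit(y2, X)$p_value, 0.005)
})

test_that("multiple correlation is non-decreasing in the predictor set", {
  set.seed(79)
  k <- 12
  X <- matrix(stats::rnorm(k * 4), ncol = 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  y <- X[, 1] - X[, 2] + stats::rnorm(k)
  rs <- vapply(1:4, function(p)
    multiple_fit(y, X[, 1:p, drop = FALSE])$multiple_r, numeric(1))
  expect_true(all(diff(rs) >= -1e-12))
})

test_that("multiple regression rejects rank-deficient designs", {
  set.seed(80)
  k <- 10
  x1 <- stats::rnorm(k)
  X <- cbind(p1 = x1, p2 = 2 * x1)
  expect_error(multiple_fit(stats::rnorm(k), X), "collinear.*p2")
  expect_error(multiple_fit(stats::rnorm(4), matrix(stats::rnorm(12), ncol = 3)),
               "more bins")
})
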
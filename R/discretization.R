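#' Sturges' formula for class selection
#'
#' Computes `log2(n) + 1` and its ceiling, the number of histogram classes
#' suggested by Sturges' rule for a sample of size `n`. Both the raw value
#' and the integer class count are returned, since the raw value (e.g. 11.4
#' for n = 1327) is itself reported when choosing a common bin count across
#' strata.
#'
#' @param n Positive integer sample size.
#' @return A list with `raw` (`log2(n) + 1`) and `k` (`ceiling(raw)`).
#' @examples
#' sturges(1327)  # raw 11.37, k 12
#' @export
sturges <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != floor(n)) {
    stop("`n` must be a single integer >= 1")
  }
  raw <- log2(n) + 1
  list(raw = raw, k = as.integer(ceiling(raw)))
}

# Exact 1-D clustering by dynamic programming over the sorted values.
# Clusters of an optimal 1-D k-means solution are contiguous intervals of the
# sorted data, so DP over segment boundaries finds the global optimum.
# objective "means": within-segment sum of squared deviations from the mean;
# "medoids": sum of absolute deviations from the segment (lower) median.
cluster_1d_dp <- function(xs, k, objective = c("means", "medoids")) {
  objective <- match.arg(objective)
  n <- length(xs)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))

  seg_cost <- function(m, i) {
    # vectorized over m (segment starts), fixed end i
    len <- i - m + 1
    if (objective == "means") {
      s <- cs[i + 1L] - cs[m]
      pmax(0, (cs2[i + 1L] - cs2[m]) - s^2 / len)
    } else {
      h <- m + (i - m) %/% 2L # lower median index
      xh <- xs[h]
      left <- xh * (h - m + 1) - (cs[h + 1L] - cs[m])
      right <- (cs[i + 1L] - cs[h + 1L]) - xh * (i - h)
      pmax(0, left + right)
    }
  }

  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(1L, nrow = k, ncol = n)
  for (i in seq_len(n)) D[1L, i] <- seg_cost(1L, i)
  if (k > 1L) {
    for (j in 2:k) {
      for (i in j:n) {
        ms <- j:i
        tot <- D[j - 1L, ms - 1L] + seg_cost(ms, i)
        w <- which.min(tot)
        D[j, i] <- tot[[w]]
        B[j, i] <- ms[[w]]
      }
    }
  }

  # backtrack segment starts
  starts <- integer(k)
  i <- n
  for (j in k:1) {
    starts[[j]] <- if (j == 1L) 1L else B[j, i]
    i <- starts[[j]] - 1L
  }
  labels_sorted <- rep(seq_len(k), times = diff(c(starts, n + 1L)))
  list(labels_sorted = labels_sorted, sse = D[k, n])
}

new_bin_assignment <- function(values, labels, k, method) {
  ok <- !is.na(labels)
  sizes <- as.integer(tabulate(labels[ok], nbins = k))
  reps <- vapply(seq_len(k), function(j) mean(values[which(labels == j)]),
                 numeric(1L))
  structure(
    list(labels = labels, k = as.integer(k), method = method,
         bin_sizes = sizes, representatives = reps,
         n = sum(ok)),
    class = "bin_assignment"
  )
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("<bin_assignment> %s, k = %d, n = %d\n", x$method, x$k, x$n))
  print(data.frame(bin = seq_len(x$k), n = x$bin_sizes,
                   mean = round(x$representatives, 4)))
  invisible(x)
}

#' Exact 1-D k-means discretization
#'
#' Partitions a continuous covariate into `k` contiguous clusters minimizing
#' the within-cluster sum of squares, solved exactly by dynamic programming
#' over the sorted values (in 1-D the optimal clusters are contiguous
#' intervals, so the DP attains the global optimum and no random
#' initialization is involved). A `"medoids"` objective (sum of absolute
#' deviations from the cluster median) is available as an alternative
#' reading of medoid partitioning.
#'
#' @param values Numeric vector; `NA`s are excluded and keep `NA` labels.
#' @param k Number of bins, at most the number of distinct finite values.
#' @param seed Accepted for interface compatibility and ignored: the exact
#'   solver is deterministic.
#' @param objective `"means"` (default) or `"medoids"`.
#' @return An object of class `bin_assignment`: per-observation `labels` in
#'   `1..k` ascending with value, `bin_sizes`, `representatives` (bin
#'   means), `n` (non-missing count), plus `sse` as an attribute.
#' @examples
#' kmeans_1d(c(0, 0, 10, 10), k = 2)
#' @export
kmeans_1d <- function(values, k, seed = NULL, objective = c("means", "medoids")) {
  objective <- match.arg(objective)
  stopifnot(is.numeric(values))
  k <- as.integer(k)
  idx <- which(!is.na(values))
  x <- values[idx]
  if (any(!is.finite(x))) stop("values must be finite or NA")
  if (k < 1L) stop("`k` must be >= 1")
  n_distinct <- length(unique(x))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the %d distinct values", k, n_distinct))
  }

  ord <- order(x)
  dp <- cluster_1d_dp(x[ord], k, objective)
  labels <- rep(NA_integer_, length(values))
  labels[idx[ord]] <- dp$labels_sorted

  out <- new_bin_assignment(values, labels, k, paste0("kmeans_1d (", objective, ")"))
  attr(out, "sse") <- dp$sse
  out
}

#' Equal-frequency discretization
#'
#' Splits the sorted observations into `k` contiguous bins whose sizes differ
#' by at most one, with the larger bins first; used to stratify age, whose
#' truncated range makes distance-based clustering uninformative. Ties keep
#' their stable sort order.
#'
#' @param values Numeric vector; `NA`s are excluded and keep `NA` labels.
#' @param k Number of bins, at most the number of non-missing observations.
#' @return A `bin_assignment` (see [kmeans_1d()]).
#' @examples
#' table(equal_frequency_bins(rnorm(100), 12)$labels)
#' @export
equal_frequency_bins <- function(values, k) {
  stopifnot(is.numeric(values))
  k <- as.integer(k)
  idx <- which(!is.na(values))
  n <- length(idx)
  if (k < 1L) stop("`k` must be >= 1")
  if (n < k) stop(sprintf("n = %d observations is fewer than k = %d bins", n, k))

  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ord <- order(values[idx]) # stable for ties
  labels <- rep(NA_integer_, length(values))
  labels[idx[ord]] <- rep(seq_len(k), times = sizes)
  new_bin_assignment(values, labels, k, "equal_frequency")
}
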
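# Independent oracles used to check the package implementations. These are
# deliberately written as naive double loops / closed forms that share no
# code with the package internals.

# Brute-force single-neighbor Relief sweep over every case: explicit
# distance loops, nearest hit/miss by scanning, lowest-index tie-break.
oracle_relief_nearest <- function(x, y) {
  x <- unname(x)
  n <- nrow(x)
  T <- n
  w <- numeric(ncol(x))
  euclid <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  for (i in seq_len(n)) {
    best_hit <- NA_integer_; best_hit_d <- Inf
    best_miss <- NA_integer_; best_miss_d <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- euclid(i, j)
      if (y[j] == y[i]) {
        if (dij < best_hit_d) { best_hit_d <- dij; best_hit <- j }
      } else {
        if (dij < best_miss_d) { best_miss_d <- dij; best_miss <- j }
      }
    }
    w <- w + abs(x[i, ] - x[best_miss, ]) / T - abs(x[i, ] - x[best_hit, ]) / T
  }
  w
}

# Mantegna scale via log-gamma (independent of the package's gamma() call).
oracle_sigma_mu <- function(beta) {
  num <- exp(lgamma(1 + beta)) * sin(pi * beta / 2)
  den <- exp(lgamma((1 + beta) / 2)) * beta * 2^((beta - 1) / 2)
  (num / den)^(1 / beta)
}

# Exhaustive enumeration of every nonempty subset of d features, scored with
# subset_fitness on a fixed fold plan. Returns the global optimum.
oracle_best_subset <- function(data, folds, beta = 0.2, classifier = "surrogate") {
  d <- ncol(data$features)
  stopifnot(d <= 12)
  best <- -Inf
  best_bits <- NULL
  for (code in seq_len(2^d - 1L)) {
    bits <- as.integer(intToBits(code)[seq_len(d)])
    f <- subset_fitness(data, bits, beta = beta, folds = folds,
                        classifier = classifier)
    if (f > best) { best <- f; best_bits <- bits }
  }
  list(fitness = best, bits = best_bits)
}

# Random small binary-labeled instance with at least `min_class` cases per
# class (features uniform on [0,1]).
random_instance <- function(n, d, min_class = 2L) {
  repeat {
    y <- rbinom(n, 1L, 0.5)
    if (min(sum(y), n - sum(y)) >= min_class) break
  }
  x <- matrix(runif(n * d), n, d)
  fs_dataset(x, y)
}
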
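# Relief feature weighting. The weight of feature j accumulates, over
# sampled cases, the absolute difference to the nearest case of the other
# class (nearest miss) minus the difference to the nearest case of the same
# class (nearest hit), each divided by the number of sampled cases T. A
# feature that separates the classes collects positive weight; one on which
# same-class neighbors disagree collects negative weight.

#' Compute Relief feature weights
#'
#' The `nearest` variant updates, for each sampled case x,
#' `w_j <- w_j + |x_j - NM(x)_j| / T - |x_j - NH(x)_j| / T`
#' with NH/NM the Euclidean-nearest same-/other-class case (the case itself
#' excluded from the hit search). The `knn` variant averages the update over
#' the `k` nearest hits and `k` nearest misses, so the two variants coincide
#' at `k = 1`. Nearest-neighbor ties are broken by lowest case index.
#'
#' Weights are scale-sensitive; run [normalize_features()] first (a warning
#' is emitted when features do not look like they share a common scale).
#'
#' @param data an [fs_dataset()].
#' @param variant `"nearest"` (single neighbor) or `"knn"`.
#' @param k neighbor count for the `knn` variant (default 3).
#' @param sampling `"all_cases"` (deterministic sweep over every case,
#'   `T = n`; the default) or `"random"` (sample `T` cases with replacement).
#' @param T number of cases sampled; defaults to `n`.
#' @param seed seed for `sampling = "random"`.
#' @return An object of class `relief_weights`: list with `w` (named
#'   length-d numeric; may contain negative entries), `variant`, `k`, `T`.
#' @export
relief_weights <- function(data, variant = c("nearest", "knn"), k = 3L,
                           sampling = c("all_cases", "random"), T = NULL,
                           seed = 1L) {
  stopifnot(inherits(data, "fs_dataset"))
  variant <- match.arg(variant)
  sampling <- match.arg(sampling)
  x <- data$features
  y <- data$labels
  n <- nrow(x)
  d <- ncol(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  need <- if (variant == "nearest") 1L else k
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  # hits exclude the case itself, so a class must have need+1 members to
  # supply `need` hits for its own cases
  if (min(n0, n1) < need + 1L)
    stop("insufficient class support for Relief (need ", need + 1L,
         " cases per class)")
  rng <- apply(x, 2L, function(col) diff(range(col)))
  if (any(rng > 0) && (max(rng[rng > 0]) / min(rng[rng > 0]) > 100))
    warning("features span very different ranges; consider normalize_features()")

  if (sampling == "all_cases") {
    picks <- seq_len(n)
    if (is.null(T)) T <- n
  } else {
    if (is.null(T)) T <- n
    picks <- with_seed(seed, sample.int(n, size = T, replace = TRUE))
  }
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")

  d2 <- as.matrix(stats::dist(x))  # Euclidean distances, case x case
  w <- numeric(d)
  for (i in picks) {
    same <- which(y == y[i])
    same <- same[same != i]
    other <- which(y != y[i])
    if (variant == "nearest") {
      nh <- same[which.min(d2[i, same])]    # which.min keeps lowest index on ties
      nm <- other[which.min(d2[i, other])]
      w <- w + abs(x[i, ] - x[nm, ]) / T - abs(x[i, ] - x[nh, ]) / T
    } else {
      hit_ord <- same[order(d2[i, same], same)][seq_len(k)]
      miss_ord <- other[order(d2[i, other], other)][seq_len(k)]
      for (z in miss_ord) w <- w + abs(x[i, ] - x[z, ]) / (T * k)
      for (z in hit_ord) w <- w - abs(x[i, ] - x[z, ]) / (T * k)
    }
  }
  structure(list(w = stats::setNames(w, data$feature_names),
                 variant = variant, k = if (variant == "knn") k else 1L,
                 T = T, sampling = sampling),
            class = "relief_weights")
}

#' @export
print.relief_weights <- function(x, ...) {
  cat("Relief weights (", x$variant, " variant, T = ", x$T, ")\n", sep = "")
  print(utils::head(sort(x$w, decreasing = TRUE), 10L))
  invisible(x)
}

#' Map Relief weights to transfer-function coefficients
#'
#' The weight-parameterized transfer function uses a per-feature sigmoid
#' coefficient gamma. The default `identity` scaling passes the Relief
#' weights through unchanged (`gamma_j = w_j`); `minmax` rescales linearly
#' to `[-1, 1]`; `clip` truncates to `range`.
#'
#' @param w a `relief_weights` object or bare numeric vector.
#' @param scaling `"identity"`, `"minmax"` or `"clip"`.
#' @param range length-2 numeric, the clip interval.
#' @return Numeric vector of per-feature gamma coefficients, with the
#'   scaling recorded in the `"scaling"` attribute.
#' @export
weights_to_gamma <- function(w, scaling = c("identity", "minmax", "clip"),
                             range = c(-1, 1)) {
  scaling <- match.arg(scaling)
  wv <- if (inherits(w, "relief_weights")) w$w else as.numeric(w)
  g <- switch(scaling,
    identity = wv,
    minmax = {
      lo <- min(wv); hi <- max(wv)
      if (hi == lo) rep(0, length(wv)) else 2 * (wv - lo) / (hi - lo) - 1
    },
    clip = pmin(pmax(wv, range[1L]), range[2L]))
  attr(g, "scaling") <- scaling
  g
}

#' Export Relief weights as a two-column CSV
#'
#' @param w a `relief_weights` object.
#' @param path output file path.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "relief_weights"))
  utils::write.csv(data.frame(feature_name = names(w$w), weight = unname(w$w)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
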
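# Elitist genetic layer: roulette-wheel selection, single-point crossover,
# and the regeneration step that replaces classical cuckoo nest abandonment
# — the worst fraction of non-elite nests is rebuilt from offspring of
# fitness-proportionally selected parents, while the elite nest is copied
# through untouched.

#' Roulette-wheel selection probabilities
#'
#' `p_i = f_i / sum(f)` with cumulative probabilities `q_i = sum_{j<=i} p_j`;
#' the last cumulative entry is forced to exactly 1.
#'
#' @param fitnesses strictly positive fitness values.
#' @return List with `p` (selection probabilities) and `q` (cumulative).
#' @export
roulette_probabilities <- function(fitnesses) {
  if (length(fitnesses) < 1L || any(!is.finite(fitnesses)) || any(fitnesses <= 0))
    stop("roulette requires positive fitness")
  p <- fitnesses / sum(fitnesses)
  q <- cumsum(p)
  q[length(q)] <- 1
  list(p = p, q = q)
}

#' Draw individuals by roulette-wheel selection
#'
#' Inverts the cumulative distribution against independent uniforms:
#' individual i is picked when `q_{i-1} < u <= q_i`. Draws are with
#' replacement and consume one uniform each, in order.
#'
#' @param fitnesses strictly positive fitness values.
#' @param count number of draws.
#' @return Integer vector of `count` selected indices.
#' @export
roulette_select <- function(fitnesses, count) {
  q <- roulette_probabilities(fitnesses)$q
  u <- stats::runif(count)
  findInterval(u, q, left.open = TRUE) + 1L
}

#' Single-point crossover of two bit vectors
#'
#' A cut point c is drawn uniformly from `1..(d-1)`; the offspring exchange
#' the suffixes after position c.
#'
#' @param a,b equal-length 0/1 vectors with `d >= 2`.
#' @param point optional forced cut point (test hook).
#' @return List of the two offspring bit vectors.
#' @export
crossover_single_point <- function(a, b, point = NULL) {
  d <- length(a)
  if (length(b) != d) stop("parents must have equal length")
  if (d < 2L) stop("crossover needs at least 2 bits")
  c_pt <- if (is.null(point)) sample.int(d - 1L, 1L) else as.integer(point)
  if (c_pt < 1L || c_pt > d - 1L) stop("crossover point out of range")
  tail_idx <- (c_pt + 1L):d
  o1 <- a; o2 <- b
  o1[tail_idx] <- b[tail_idx]
  o2[tail_idx] <- a[tail_idx]
  list(o1, o2)
}

#' Elite-preserving regeneration of a nest population
#'
#' The elite (best) nest is copied through untouched. A fraction `p_r` of
#' the worst non-elite nests — `floor(p_r * (n_pop - 1))` of them — is
#' replaced by offspring of roulette-selected parent pairs; each pair is
#' crossed with probability `p_c` and cloned otherwise. Replacements are
#' evaluated with `fitness_fn` and the elite index refreshed. Population
#' size never changes and the best fitness never decreases.
#'
#' @param bits_mat n_pop x d 0/1 matrix of nests.
#' @param fitnesses length-n_pop evaluated fitness vector (positive).
#' @param p_c crossover probability per parent pair.
#' @param p_r fraction of worst non-elite nests regenerated.
#' @param fitness_fn function(bits) -> positive scalar fitness.
#' @param repair function applied to each offspring before evaluation
#'   (identity by default); used upstream to fix all-zero subsets, whose
#'   fitness is undefined.
#' @return List with updated `bits`, `fitnesses` and `elite` index.
#' @export
elite_regenerate <- function(bits_mat, fitnesses, p_c, p_r, fitness_fn,
                             repair = identity) {
  stopifnot(is.matrix(bits_mat), length(fitnesses) == nrow(bits_mat),
            p_c >= 0, p_c <= 1, p_r >= 0, p_r <= 1)
  n_pop <- nrow(bits_mat)
  elite <- elite_index(fitnesses, bits_mat)
  n_rep <- floor(p_r * (n_pop - 1L))
  if (n_rep >= 1L) {
    non_elite <- setdiff(seq_len(n_pop), elite)
    worst <- non_elite[order(fitnesses[non_elite])][seq_len(n_rep)]
    offspring <- vector("list", 0L)
    while (length(offspring) < n_rep) {
      parents <- roulette_select(fitnesses, 2L)
      a <- bits_mat[parents[1L], ]
      b <- bits_mat[parents[2L], ]
      kids <- if (ncol(bits_mat) >= 2L && stats::runif(1L) < p_c)
        crossover_single_point(a, b) else list(a, b)
      offspring <- c(offspring, kids)
    }
    for (i in seq_len(n_rep)) {
      child <- repair(offspring[[i]])
      bits_mat[worst[i], ] <- child
      fitnesses[worst[i]] <- fitness_fn(child)
    }
    elite <- elite_index(fitnesses, bits_mat)
  }
  list(bits = bits_mat, fitnesses = fitnesses, elite = elite)
}
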
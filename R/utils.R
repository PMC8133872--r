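# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Key for the fitness cache: compact string form of a bit vector.
bits_key <- function(bits) {
  rawToChar(as.raw(65L + bits))  # 'A'/'B' string; cheap and collision-free
}

# Index of the best nest: max fitness, ties broken by fewer selected
# features, then by lowest index.
elite_index <- function(fitnesses, bits_mat) {
  best <- which(fitnesses == max(fitnesses))
  if (length(best) > 1L) {
    sizes <- rowSums(bits_mat[best, , drop = FALSE])
    best <- best[sizes == min(sizes)]
  }
  best[1L]
}
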
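# Search engines behind the common `feature_select()` surface. All four are
# elitist: the best-so-far subset can never be lost, so the best-fitness
# trajectory is non-decreasing. Candidate subsets that binarize to all
# zeros are repaired before evaluation (the fitness of an empty subset is
# undefined): the elite hybrid search sets the single highest-gamma bit,
# the baselines set one uniformly random bit.

default_control <- function(algorithm) {
  switch(algorithm,
    ehbcs = list(alpha = 1, levy_beta = 1.5, p_c = 0.5, p_r = 0.3,
                 relief_variant = "knn", relief_k = 3L,
                 gamma_scaling = "identity", greedy_accept = TRUE),
    bcs = list(alpha = 1, levy_beta = 1.5, p_a = 0.25, greedy_accept = TRUE),
    bga = list(p_c = 0.8, p_m = 0.1),
    bpso = list(c1 = 1, c2 = 2, omega = 0.9, v_max = 6),
    stop("unknown algorithm: ", algorithm))
}

#' Search-control parameters
#'
#' Merges user overrides onto the per-algorithm defaults: elite hybrid
#' binary cuckoo search `alpha = 1, p_c = 0.5, p_r = 0.3, relief_k = 3`;
#' binary genetic algorithm `p_c = 0.8, p_m = 0.1`; binary particle swarm
#' `c1 = 1, c2 = 2, omega = 0.9, v_max = 6`; binary cuckoo search
#' `alpha = 1, p_a = 0.25`.
#'
#' @param algorithm one of `"ehbcs"`, `"bcs"`, `"bga"`, `"bpso"`.
#' @param ... named overrides of the algorithm's parameters.
#' @return Named list of control parameters.
#' @export
fs_control <- function(algorithm = "ehbcs", ...) {
  ctl <- default_control(algorithm)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(ctl))
  if (length(unknown)) stop("unknown control parameter(s): ",
                            paste(unknown, collapse = ", "))
  ctl[names(dots)] <- dots
  for (p in intersect(c("p_c", "p_r", "p_a", "p_m"), names(ctl)))
    if (ctl[[p]] < 0 || ctl[[p]] > 1) stop(p, " must lie in [0, 1]")
  ctl
}

init_population <- function(n_pop, d, repair) {
  pop <- matrix(stats::rbinom(n_pop * d, 1L, 0.5), n_pop, d)
  for (i in seq_len(n_pop)) pop[i, ] <- repair(pop[i, ])
  pop
}

make_repair <- function(d, gammas = NULL) {
  if (is.null(gammas)) {
    function(bits) {
      if (sum(bits) == 0L) bits[sample.int(d, 1L)] <- 1L
      bits
    }
  } else {
    top <- which.max(gammas)
    function(bits) {
      if (sum(bits) == 0L) bits[top] <- 1L
      bits
    }
  }
}

# Shared engine state bookkeeping: best-ever subset plus trajectory.
track_best <- function(state, pop, fit) {
  e <- elite_index(fit, pop)
  if (fit[e] > state$best_fitness ||
      (fit[e] == state$best_fitness && sum(pop[e, ]) < sum(state$best_bits))) {
    state$best_fitness <- fit[e]
    state$best_bits <- pop[e, ]
  }
  state
}

engine_ehbcs <- function(d, n_pop, n_iter, fitness_fn, ctl, gammas) {
  repair <- make_repair(d, gammas)
  pop <- init_population(n_pop, d, repair)
  fit <- apply(pop, 1L, fitness_fn)
  state <- list(best_bits = pop[elite_index(fit, pop), ],
                best_fitness = max(fit))
  traj <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    elite <- elite_index(fit, pop)
    for (i in setdiff(seq_len(n_pop), elite)) {
      cand <- repair(binarize_steps(levy_steps(d, ctl$alpha, ctl$levy_beta),
                                    gammas))
      f_new <- fitness_fn(cand)
      if (!isTRUE(ctl$greedy_accept) || f_new > fit[i]) {
        pop[i, ] <- cand
        fit[i] <- f_new
      }
    }
    reg <- elite_regenerate(pop, fit, ctl$p_c, ctl$p_r, fitness_fn, repair)
    pop <- reg$bits
    fit <- reg$fitnesses
    state <- track_best(state, pop, fit)
    traj[t] <- state$best_fitness
  }
  c(state, list(trajectory = traj))
}

engine_bcs <- function(d, n_pop, n_iter, fitness_fn, ctl) {
  repair <- make_repair(d)
  pop <- init_population(n_pop, d, repair)
  fit <- apply(pop, 1L, fitness_fn)
  state <- list(best_bits = pop[elite_index(fit, pop), ],
                best_fitness = max(fit))
  traj <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    elite <- elite_index(fit, pop)
    for (i in setdiff(seq_len(n_pop), elite)) {
      cand <- repair(binarize_steps(levy_steps(d, ctl$alpha, ctl$levy_beta), 1))
      f_new <- fitness_fn(cand)
      if (!isTRUE(ctl$greedy_accept) || f_new > fit[i]) {
        pop[i, ] <- cand
        fit[i] <- f_new
      }
    }
    # abandonment: the worst fraction p_a of non-elite nests is rebuilt at
    # random positions
    n_ab <- floor(ctl$p_a * (n_pop - 1L))
    if (n_ab >= 1L) {
      elite <- elite_index(fit, pop)
      non_elite <- setdiff(seq_len(n_pop), elite)
      worst <- non_elite[order(fit[non_elite])][seq_len(n_ab)]
      for (i in worst) {
        pop[i, ] <- repair(stats::rbinom(d, 1L, 0.5))
        fit[i] <- fitness_fn(pop[i, ])
      }
    }
    state <- track_best(state, pop, fit)
    traj[t] <- state$best_fitness
  }
  c(state, list(trajectory = traj))
}

engine_bga <- function(d, n_pop, n_iter, fitness_fn, ctl) {
  repair <- make_repair(d)
  pop <- init_population(n_pop, d, repair)
  fit <- apply(pop, 1L, fitness_fn)
  state <- list(best_bits = pop[elite_index(fit, pop), ],
                best_fitness = max(fit))
  traj <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    elite <- elite_index(fit, pop)
    new_pop <- matrix(0L, n_pop, d)
    new_fit <- numeric(n_pop)
    new_pop[1L, ] <- pop[elite, ]   # elitism of one
    new_fit[1L] <- fit[elite]
    slot <- 2L
    while (slot <= n_pop) {
      parents <- roulette_select(fit, 2L)
      a <- pop[parents[1L], ]; b <- pop[parents[2L], ]
      kids <- if (d >= 2L && stats::runif(1L) < ctl$p_c)
        crossover_single_point(a, b) else list(a, b)
      for (kid in kids) {
        if (slot > n_pop) break
        flip <- stats::runif(d) < ctl$p_m
        kid[flip] <- 1L - kid[flip]
        kid <- repair(kid)
        new_pop[slot, ] <- kid
        new_fit[slot] <- fitness_fn(kid)
        slot <- slot + 1L
      }
    }
    pop <- new_pop
    fit <- new_fit
    state <- track_best(state, pop, fit)
    traj[t] <- state$best_fitness
  }
  c(state, list(trajectory = traj))
}

engine_bpso <- function(d, n_pop, n_iter, fitness_fn, ctl) {
  repair <- make_repair(d)
  pop <- init_population(n_pop, d, repair)
  fit <- apply(pop, 1L, fitness_fn)
  vel <- matrix(0, n_pop, d)
  pbest <- pop
  pbest_fit <- fit
  g <- elite_index(fit, pop)
  gbest <- pop[g, ]
  gbest_fit <- fit[g]
  traj <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    for (i in seq_len(n_pop)) {
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      vel[i, ] <- ctl$omega * vel[i, ] +
        ctl$c1 * r1 * (pbest[i, ] - pop[i, ]) +
        ctl$c2 * r2 * (gbest - pop[i, ])
      vel[i, ] <- pmin(pmax(vel[i, ], -ctl$v_max), ctl$v_max)
      pop[i, ] <- repair(as.integer(stats::runif(d) <= stats::plogis(vel[i, ])))
      fit[i] <- fitness_fn(pop[i, ])
      if (fit[i] > pbest_fit[i]) {
        pbest[i, ] <- pop[i, ]
        pbest_fit[i] <- fit[i]
      }
      if (fit[i] > gbest_fit) {
        gbest <- pop[i, ]
        gbest_fit <- fit[i]
      }
    }
    traj[t] <- gbest_fit
  }
  list(best_bits = gbest, best_fitness = gbest_fit, trajectory = traj)
}

run_engine <- function(algorithm, d, n_pop, n_iter, fitness_fn, ctl,
                       gammas = NULL) {
  switch(algorithm,
    ehbcs = engine_ehbcs(d, n_pop, n_iter, fitness_fn, ctl, gammas),
    bcs = engine_bcs(d, n_pop, n_iter, fitness_fn, ctl),
    bga = engine_bga(d, n_pop, n_iter, fitness_fn, ctl),
    bpso = engine_bpso(d, n_pop, n_iter, fitness_fn, ctl))
}
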
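# User-facing fitting surface: feature_select() runs one wrapper
# feature-selection search and returns a classed result with the usual
# modelling methods.

#' Wrapper feature selection by elite hybrid binary cuckoo search
#'
#' Searches the space of feature subsets for one that maximizes the fitness
#' `beta * (d - s) / d + (1 - beta) * acc`, where `acc` is the
#' cross-validated accuracy of a classifier trained on the subset and the
#' first term rewards feature reduction. Four elitist search algorithms are
#' available behind the same interface:
#'
#' * `"ehbcs"` — elite hybrid binary cuckoo search: Relief feature weights
#'   set the per-feature sigmoid coefficient that binarizes Mantegna
#'   Levy-flight steps (heavily weighted features are selected with higher
#'   probability, negatively weighted ones with probability below 0.5), the
#'   best nest is never perturbed, and an elitist
#'   roulette-selection/single-point-crossover step regenerates the worst
#'   fraction `p_r` of nests in place of the classical abandonment step.
#' * `"bcs"` — plain binary cuckoo search (unit sigmoid coefficient, random
#'   abandonment of the worst fraction `p_a`).
#' * `"bga"` — generational binary genetic algorithm with roulette
#'   selection, single-point crossover, per-bit mutation, elitism of one.
#' * `"bpso"` — binary particle swarm optimization with sigmoid velocity
#'   binarization.
#'
#' @param x an [fs_dataset()], a numeric matrix/data frame of features, or a
#'   formula.
#' @param ... further arguments passed to the default method.
#' @return An object of class `feature_select`; see Details.
#'
#' @details The returned object has elements `best_bits` (0/1 selection
#' vector), `selected` (selected feature names), `best_fitness`,
#' `trajectory` (best-so-far fitness per iteration, non-decreasing),
#' `report` (a `metric_report` re-evaluating the final subset on the same
#' folds), `weights` (Relief weights, elite hybrid search only),
#' `n_evaluations`/`n_cache_hits`, the resolved `control` list and `seed`.
#' Methods: [print()], [summary()], [coef()] (per-feature Relief weights or
#' the selection indicator), [predict()] (classifies new cases with the
#' subset's classifier refit on all training data), and [plot()] (fitness
#' trajectory). Identical inputs and `seed` reproduce the result exactly.
#' @export
feature_select <- function(x, ...) UseMethod("feature_select")

#' @rdname feature_select
#' @param formula a two-sided formula `label ~ .` or `label ~ f1 + f2 + ...`.
#' @param data data frame holding the variables of `formula`.
#' @export
feature_select.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[-1L]
  out <- feature_select.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname feature_select
#' @export
feature_select.fs_dataset <- function(x, ...) {
  feature_select_run(x, ...)
}

#' @rdname feature_select
#' @param y class labels (two distinct values), used when `x` is a matrix
#'   or data frame.
#' @export
feature_select.default <- function(x, y, ...) {
  feature_select_run(fs_dataset(x, y), ...)
}

#' @rdname feature_select
#' @param algorithm `"ehbcs"` (default), `"bcs"`, `"bga"` or `"bpso"`.
#' @param n_pop population size (default 30).
#' @param n_iter iteration budget (default 100).
#' @param beta fitness weight of the feature-reduction term (default 0.2;
#'   0 optimizes plain accuracy).
#' @param classifier `"auto"` (SVM with kernel picked by dimensionality:
#'   radial below 2000 features, linear above), `"svm_rbf"`, `"svm_linear"`
#'   or the fast `"surrogate"` nearest-centroid classifier.
#' @param normalize feature normalization applied up front (`"minmax"`
#'   default, `"zscore"`, `"none"`).
#' @param folds optional `fold_plan`; by default built from `seed` with the
#'   5-below-100-cases / 10-otherwise rule.
#' @param seed integer seed; every random draw of the run flows from it.
#' @param control named list of algorithm parameters, merged onto
#'   [fs_control()] defaults.
feature_select_run <- function(x, algorithm = c("ehbcs", "bcs", "bga", "bpso"),
                               n_pop = 30L, n_iter = 100L, beta = 0.2,
                               classifier = "auto",
                               normalize = c("minmax", "zscore", "none"),
                               folds = NULL, seed = 1L, control = list()) {
  stopifnot(inherits(x, "fs_dataset"))
  algorithm <- match.arg(algorithm)
  normalize <- match.arg(normalize)
  n_pop <- as.integer(n_pop)
  n_iter <- as.integer(n_iter)
  if (n_pop < 2L) stop("n_pop must be >= 2")
  if (n_iter < 0L) stop("n_iter must be >= 0")
  ctl <- do.call(fs_control, c(list(algorithm = algorithm), control))
  data <- normalize_features(x, normalize)
  d <- ncol(data$features)
  if (classifier == "auto") classifier <- classifier_default(d)

  weights <- NULL
  gammas <- NULL
  if (algorithm == "ehbcs") {
    weights <- relief_weights(data, variant = ctl$relief_variant,
                              k = ctl$relief_k)
    gammas <- weights_to_gamma(weights, scaling = ctl$gamma_scaling)
  }
  fitness_fn <- make_fitness(data, beta = beta, folds = folds,
                             classifier = classifier, seed = seed)
  t0 <- proc.time()[["elapsed"]]
  res <- with_seed(seed,
                   run_engine(algorithm, d, n_pop, n_iter, fitness_fn, ctl,
                              gammas))
  elapsed <- proc.time()[["elapsed"]] - t0
  counters <- attr(fitness_fn, "counters")()
  report <- cv_evaluate(data, res$best_bits, folds = attr(fitness_fn, "folds"),
                        classifier = classifier)
  structure(
    list(algorithm = algorithm,
         best_bits = res$best_bits,
         selected = data$feature_names[res$best_bits == 1L],
         best_fitness = res$best_fitness,
         trajectory = res$trajectory,
         report = report,
         weights = weights,
         n_evaluations = counters$n_evaluations,
         n_cache_hits = counters$n_cache_hits,
         n_pop = n_pop, n_iter = n_iter, beta = beta,
         classifier = classifier, normalize = normalize,
         control = ctl, seed = as.integer(seed),
         folds = attr(fitness_fn, "folds"),
         data = data, elapsed = elapsed,
         call = match.call()),
    class = "feature_select")
}

#' @export
print.feature_select <- function(x, ...) {
  d <- length(x$best_bits)
  cat("Feature selection by ", toupper(x$algorithm), "\n", sep = "")
  cat("  ", sum(x$best_bits), " of ", d, " features selected (",
      sprintf("%.1f%%", 100 * (d - sum(x$best_bits)) / d), " size reduction)\n",
      sep = "")
  cat("  best fitness ", sprintf("%.4f", x$best_fitness),
      " | CV accuracy ", sprintf("%.4f", x$report$means[["accuracy"]]),
      " (", x$report$k, "-fold, ", x$classifier, ")\n", sep = "")
  cat("  ", x$n_evaluations, " fitness evaluations (+", x$n_cache_hits,
      " cache hits), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.feature_select <- function(object, ...) {
  structure(list(fit = object), class = "summary.feature_select")
}

#' @export
print.summary.feature_select <- function(x, ...) {
  print(x$fit)
  cat("\nSelected features:\n")
  print(x$fit$selected)
  cat("\nCross-validated metrics of the selected subset:\n")
  print(round(x$fit$report$means, 4))
  if (!is.null(x$fit$weights)) {
    cat("\nTop Relief weights:\n")
    print(round(utils::head(sort(x$fit$weights$w, decreasing = TRUE), 10L), 4))
  }
  invisible(x)
}

#' Extract per-feature scores from a feature-selection fit
#'
#' For the elite hybrid search this is the named Relief weight vector that
#' parameterized the transfer function; for the baselines (which use no
#' weighting) it is the 0/1 selection indicator.
#'
#' @param object a `feature_select` fit.
#' @param ... unused.
#' @return Named numeric vector of length d.
#' @export
coef.feature_select <- function(object, ...) {
  if (!is.null(object$weights)) object$weights$w
  else stats::setNames(as.numeric(object$best_bits), object$data$feature_names)
}

#' Predict class labels with the selected feature subset
#'
#' Refits the run's classifier on the full (normalized) training data
#' restricted to the selected features and classifies `newdata`, which is
#' normalized with the training scale parameters.
#'
#' @param object a `feature_select` fit.
#' @param newdata numeric matrix or data frame with the training columns.
#' @param ... unused.
#' @return Factor of predicted labels on the original label values.
#' @export
predict.feature_select <- function(object, newdata, ...) {
  data <- object$data
  nd <- as.matrix(newdata[, data$feature_names, drop = FALSE])
  storage.mode(nd) <- "double"
  sc <- attr(data, "scaling")
  if (!is.null(sc)) {
    if (sc$method == "minmax") {
      rng <- ifelse(sc$range == 0, 1, sc$range)
      nd <- sweep(sweep(nd, 2L, sc$min, "-"), 2L, rng, "/")
      nd[, sc$range == 0] <- 0
    } else {
      nd <- sweep(sweep(nd, 2L, sc$mean, "-"), 2L, sc$sd, "/")
    }
  }
  sel <- object$best_bits == 1L
  xtr <- data$features[, sel, drop = FALSE]
  pred <- switch(object$classifier,
    surrogate = fit_predict_centroid(xtr, data$labels, nd[, sel, drop = FALSE]),
    svm_rbf = fit_predict_svm(xtr, data$labels, nd[, sel, drop = FALSE], "radial"),
    svm_linear = fit_predict_svm(xtr, data$labels, nd[, sel, drop = FALSE], "linear"))
  factor(data$label_map[as.character(pred)], levels = unname(data$label_map))
}

#' Plot the best-fitness trajectory of a feature-selection run
#'
#' @param x a `feature_select` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.feature_select <- function(x, ...) {
  if (length(x$trajectory) == 0L) {
    warning("no iterations were run; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = paste0(toupper(x$algorithm), " search trajectory"), ...)
  invisible(x)
}
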
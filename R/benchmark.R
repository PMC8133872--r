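# Repeated-runs benchmark harness: each algorithm is run R times (seeds
# seed, seed+1, ...) against a fold plan fixed once for the whole
# benchmark, so algorithm comparisons are paired. Per algorithm it reports
# average / max / min accuracy, the population standard deviation over the
# run accuracies, the mean selected-subset size, averaged sensitivity /
# specificity / precision / F-measure of each run's best subset, and the
# size-reduction percentage.

#' Benchmark feature-selection algorithms with repeated runs
#'
#' @param x an [fs_dataset()] (or matrix with `y` supplied).
#' @param y labels when `x` is a matrix or data frame.
#' @param algorithms character vector out of `"ehbcs"`, `"bcs"`, `"bga"`,
#'   `"bpso"`.
#' @param runs repetitions per algorithm (default 5).
#' @param n_pop,n_iter,beta,classifier,normalize passed to
#'   [feature_select()].
#' @param seed root seed; run r of every algorithm uses `seed + r - 1`.
#' @param control named list of per-algorithm control overrides, e.g.
#'   `list(ehbcs = list(p_r = 0.2))`.
#' @return Object of class `fs_benchmark`: list with `table` (one row per
#'   algorithm plus an `avg` summary row: Avgacc, Max, Min, Std, AvgN, SE,
#'   SP, Pre, F1, SizeReduction), `runs` (per-run details incl. fits) and
#'   the shared `folds`.
#' @export
fs_benchmark <- function(x, y = NULL,
                         algorithms = c("ehbcs", "bga", "bpso"),
                         runs = 5L, n_pop = 30L, n_iter = 100L, beta = 0.2,
                         classifier = "auto",
                         normalize = "minmax", seed = 1L, control = list()) {
  data <- if (inherits(x, "fs_dataset")) x else fs_dataset(x, y)
  stopifnot(runs >= 1L)
  algorithms <- match.arg(algorithms, c("ehbcs", "bcs", "bga", "bpso"),
                          several.ok = TRUE)
  norm_data <- normalize_features(data, normalize)
  folds <- make_folds(norm_data, seed = seed)
  d <- ncol(data$features)
  run_rows <- list()
  fits <- list()
  for (alg in algorithms) {
    for (r in seq_len(runs)) {
      fit <- feature_select(norm_data, algorithm = alg, n_pop = n_pop,
                            n_iter = n_iter, beta = beta,
                            classifier = classifier, normalize = "none",
                            folds = folds, seed = seed + r - 1L,
                            control = if (!is.null(control[[alg]])) control[[alg]] else list())
      m <- fit$report$means
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        algorithm = alg, run = r, seed = seed + r - 1L,
        fitness = fit$best_fitness, accuracy = m[["accuracy"]],
        n_selected = sum(fit$best_bits), se = m[["sensitivity"]],
        sp = m[["specificity"]], pre = m[["precision"]], f1 = m[["f1"]])
      fits[[paste(alg, r, sep = ".")]] <- fit
    }
  }
  run_df <- do.call(rbind, run_rows)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  agg <- do.call(rbind, lapply(algorithms, function(alg) {
    s <- run_df[run_df$algorithm == alg, ]
    data.frame(Algorithm = alg, Avgacc = mean(s$accuracy),
               Max = max(s$accuracy), Min = min(s$accuracy),
               Std = pop_sd(s$accuracy), AvgN = mean(s$n_selected),
               SE = mean(s$se), SP = mean(s$sp), Pre = mean(s$pre),
               F1 = mean(s$f1),
               SizeReduction = (d - mean(s$n_selected)) / d * 100)
  }))
  avg_row <- data.frame(Algorithm = "avg", t(colMeans(agg[-1L])))
  names(avg_row) <- names(agg)
  structure(list(table = rbind(agg, avg_row), runs = run_df, fits = fits,
                 folds = folds, d = d, n_runs = runs, seed = seed,
                 classifier = if (classifier == "auto") classifier_default(d) else classifier,
                 std_convention = "population (divide by R)"),
            class = "fs_benchmark")
}

#' @export
print.fs_benchmark <- function(x, digits = 3, ...) {
  cat("Feature-selection benchmark: ", x$n_runs, " runs per algorithm, ",
      x$folds$k, "-fold CV, ", x$classifier, " classifier\n", sep = "")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], round, digits)
  print(tab, row.names = FALSE)
  cat("Std is the population (divide-by-R) standard deviation of run accuracies\n")
  invisible(x)
}

#' Serialize a run result or benchmark to JSON
#'
#' @param x a `feature_select` or `fs_benchmark` object.
#' @param path output file path.
#' @export
write_run_json <- function(x, path) {
  out <- if (inherits(x, "feature_select")) {
    list(algorithm = x$algorithm, seed = x$seed, n_pop = x$n_pop,
         n_iter = x$n_iter, beta = x$beta, classifier = x$classifier,
         control = x$control, selected = x$selected,
         best_fitness = x$best_fitness, trajectory = x$trajectory,
         n_evaluations = x$n_evaluations, n_cache_hits = x$n_cache_hits,
         cv = as.list(x$report$means))
  } else if (inherits(x, "fs_benchmark")) {
    list(seed = x$seed, n_runs = x$n_runs, classifier = x$classifier,
         table = x$table, runs = x$runs)
  } else stop("unsupported object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
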
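# Wrapper fitness and its ingredients: per-fold confusion metrics,
# cross-validated classification with an SVM (or a fast nearest-centroid
# surrogate), and the fitness that trades classification accuracy against
# feature-subset size.

#' Confusion-matrix metrics for a single fold
#'
#' accuracy = (TP+TN)/total, sensitivity (recall) = TP/(TP+FN),
#' specificity = TN/(FP+TN), precision = TP/(TP+FP),
#' F-measure = 2 * precision * recall / (precision + recall).
#' A metric whose denominator is zero is reported as 0 and flagged in the
#' `"undefined"` attribute rather than dropped, so per-fold averages always
#' exist.
#'
#' @param tp,tn,fp,fn non-negative confusion counts, at least one positive.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, with attribute `undefined` naming flagged metrics.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total < 1) stop("empty confusion matrix")
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  acc <- (tp + tn) / total
  se <- ratio(tp, tp + fn, "sensitivity")
  sp <- ratio(tn, fp + tn, "specificity")
  pre <- ratio(tp, tp + fp, "precision")
  f1 <- if (pre + se == 0) { undef <- c(undef, "f1"); 0 } else 2 * pre * se / (pre + se)
  structure(c(accuracy = acc, sensitivity = se, specificity = sp,
              precision = pre, f1 = f1),
            undefined = undef)
}

# ---- classifier adapters ------------------------------------------------

# Nearest-centroid surrogate: assign to the class with the nearer (squared
# Euclidean) training centroid. Ties go to class 0. Orders of magnitude
# faster than an SVM and fully deterministic, which makes exhaustive-oracle
# tests feasible.
fit_predict_centroid <- function(xtr, ytr, xte) {
  m0 <- colMeans(xtr[ytr == 0L, , drop = FALSE])
  m1 <- colMeans(xtr[ytr == 1L, , drop = FALSE])
  d0 <- rowSums(sweep(xte, 2L, m0, "-")^2)
  d1 <- rowSums(sweep(xte, 2L, m1, "-")^2)
  as.integer(d1 < d0)
}

fit_predict_svm <- function(xtr, ytr, xte, kernel, cost = 1) {
  # RBF bandwidth: 1 / (n_selected_features * mean feature variance),
  # falling back to 1/d when the training block is constant
  g <- NULL
  if (kernel == "radial") {
    v <- mean(apply(xtr, 2L, stats::var))
    g <- if (is.finite(v) && v > 0) 1 / (ncol(xtr) * v) else 1 / ncol(xtr)
  }
  fit <- if (kernel == "radial")
    e1071::svm(xtr, factor(ytr, levels = c(0L, 1L)), kernel = "radial",
               cost = cost, gamma = g, scale = FALSE)
  else
    e1071::svm(xtr, factor(ytr, levels = c(0L, 1L)), kernel = "linear",
               cost = cost, scale = FALSE)
  as.integer(as.character(stats::predict(fit, xte)))
}

classifier_default <- function(d) if (d < 2000L) "svm_rbf" else "svm_linear"

#' Cross-validated evaluation of a feature subset
#'
#' Trains the classifier on the selected columns only, fold by fold, and
#' averages the per-fold confusion metrics. Class 1 of the dataset's label
#' mapping is the positive class.
#'
#' @param data an [fs_dataset()].
#' @param bits length-d 0/1 selection vector with at least one 1.
#' @param folds a `fold_plan` from [make_folds()]; built with the default
#'   rule and `seed` when omitted.
#' @param classifier `"surrogate"` (nearest centroid), `"svm_linear"` or
#'   `"svm_rbf"`; `"auto"` picks an SVM kernel by dimensionality (RBF below
#'   2000 features, linear above).
#' @param cost SVM cost parameter.
#' @param seed used only to build `folds` when not supplied.
#' @return An object of class `metric_report`: list with `folds` (per-fold
#'   data frame incl. TP/TN/FP/FN), `means` (averaged accuracy, SE, SP, Pre,
#'   F1), `n_selected`, `classifier`.
#' @export
cv_evaluate <- function(data, bits, folds = NULL, classifier = "surrogate",
                        cost = 1, seed = 1L) {
  stopifnot(inherits(data, "fs_dataset"))
  bits <- as.integer(bits)
  if (length(bits) != ncol(data$features)) stop("bits length must equal feature count")
  if (sum(bits) < 1L) stop("empty feature subset")
  if (classifier == "auto") classifier <- classifier_default(ncol(data$features))
  if (is.null(folds)) folds <- make_folds(data, seed = seed)
  x <- data$features[, bits == 1L, drop = FALSE]
  y <- data$labels
  k <- folds$k
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds$assignments == f
    xtr <- x[!te, , drop = FALSE]; ytr <- y[!te]
    xte <- x[te, , drop = FALSE]
    pred <- switch(classifier,
      surrogate = fit_predict_centroid(xtr, ytr, xte),
      svm_rbf = fit_predict_svm(xtr, ytr, xte, "radial", cost),
      svm_linear = fit_predict_svm(xtr, ytr, xte, "linear", cost),
      stop("unknown classifier: ", classifier))
    yte <- y[te]
    tp <- sum(pred == 1L & yte == 1L); tn <- sum(pred == 0L & yte == 0L)
    fp <- sum(pred == 1L & yte == 0L); fn <- sum(pred == 0L & yte == 1L)
    m <- confusion_metrics(tp, tn, fp, fn)
    rows[[f]] <- data.frame(fold = f, tp = tp, tn = tn, fp = fp, fn = fn,
                            t(m))
  }
  per_fold <- do.call(rbind, rows)
  means <- colMeans(per_fold[c("accuracy", "sensitivity", "specificity",
                               "precision", "f1")])
  structure(list(folds = per_fold, means = means, n_selected = sum(bits),
                 classifier = classifier, k = k),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(x$k, "-fold CV, ", x$classifier, " classifier, ",
      x$n_selected, " features\n", sep = "")
  print(round(x$means, 4))
  invisible(x)
}

#' Feature-subset fitness
#'
#' `f = beta * (d - s) / d + (1 - beta) * acc`, where `s` is the number of
#' selected features out of `d` and `acc` the cross-validated mean accuracy
#' of the subset. The reduction term rewards smaller subsets: of two subsets
#' with equal accuracy, the smaller one scores strictly higher for
#' `beta > 0`. `beta = 0` reduces the fitness to plain accuracy.
#'
#' @inheritParams cv_evaluate
#' @param beta reduction weight in `[0, 1]` (default 0.2).
#' @param acc optional precomputed accuracy, bypassing `cv_evaluate`.
#' @return Scalar fitness in `(0, 1]` (for any classifier no worse than
#'   chance on at least one fold).
#' @export
subset_fitness <- function(data, bits, beta = 0.2, folds = NULL,
                           classifier = "surrogate", cost = 1, seed = 1L,
                           acc = NULL) {
  stopifnot(beta >= 0, beta <= 1)
  bits <- as.integer(bits)
  d <- length(bits)
  s <- sum(bits)
  if (s < 1L) stop("empty feature subset has no fitness")
  if (is.null(acc))
    acc <- cv_evaluate(data, bits, folds = folds, classifier = classifier,
                       cost = cost, seed = seed)$means[["accuracy"]]
  beta * (d - s) / d + (1 - beta) * acc
}

# Build a caching fitness closure over a fixed dataset/fold plan. Distinct
# subsets hit the classifier once; repeats are served from the cache. The
# closure carries evaluation counters used for budget accounting.
make_fitness <- function(data, beta = 0.2, folds = NULL,
                         classifier = "surrogate", cost = 1, seed = 1L) {
  if (is.null(folds)) folds <- make_folds(data, seed = seed)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  n_eval <- 0L
  n_hit <- 0L
  fn <- function(bits) {
    key <- bits_key(bits)
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) {
      n_hit <<- n_hit + 1L
      return(hit)
    }
    n_eval <<- n_eval + 1L
    val <- subset_fitness(data, bits, beta = beta, folds = folds,
                          classifier = classifier, cost = cost)
    assign(key, val, envir = cache)
    val
  }
  attr(fn, "counters") <- function() list(n_evaluations = n_eval, n_cache_hits = n_hit)
  attr(fn, "folds") <- folds
  fn
}
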
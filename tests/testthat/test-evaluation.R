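# Confusion metrics, cross-validated evaluation, fitness, benchmark harness.

test_that("confusion metrics match hand arithmetic and flag zero denominators", {
  m <- confusion_metrics(tp = 3, fn = 1, fp = 2, tn = 4)
  expect_equal(as.numeric(m), c(0.7, 0.75, 2 / 3, 0.6, 2 / 3), tolerance = 1e-12)

  perfect <- confusion_metrics(tp = 5, tn = 7, fp = 0, fn = 0)
  expect_equal(as.numeric(perfect), rep(1, 5))
  expect_length(attr(perfect, "undefined"), 0)

  nopos <- confusion_metrics(tp = 0, tn = 6, fp = 0, fn = 2)
  expect_equal(nopos[["precision"]], 0)
  expect_true("precision" %in% attr(nopos, "undefined"))

  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("a label-equal feature classifies perfectly under every classifier", {
  set.seed(12)
  y <- rep_len(c(0, 1), 40)
  x <- cbind(y, matrix(rnorm(40 * 3), 40))
  ds <- normalize_features(fs_dataset(x, y), "minmax")
  for (clf in c("surrogate", "svm_rbf", "svm_linear")) {
    rep <- cv_evaluate(ds, c(1, 0, 0, 0), classifier = clf, seed = 2)
    expect_equal(rep$means[["accuracy"]], 1)
  }
})

test_that("pure-noise subsets classify at chance", {
  accs <- vapply(1:20, function(s) {
    syn <- generate_synthetic(n = 100, d = 10, n_informative = 2,
                              effect_size = 3, seed = 700 + s)
    cv_evaluate(syn$data, c(0, 0, rep(1, 8)),
                folds = make_folds(syn$data, seed = s),
                classifier = "surrogate")$means[["accuracy"]]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(20))
})

test_that("cv_evaluate is deterministic and bookkeeps its confusion totals", {
  syn <- generate_synthetic(n = 80, d = 6, n_informative = 2,
                            effect_size = 1.5, seed = 3)
  bits <- c(1, 1, 0, 1, 0, 0)
  r1 <- cv_evaluate(syn$data, bits, classifier = "surrogate", seed = 9)
  r2 <- cv_evaluate(syn$data, bits, classifier = "surrogate", seed = 9)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$means, r2$means)
  # per-fold identity: acc * total = TP + TN exactly
  with(r1$folds, expect_equal(accuracy * (tp + tn + fp + fn), tp + tn))
  expect_error(cv_evaluate(syn$data, rep(0, 6)), "empty feature subset")
})

test_that("fitness combines accuracy with the reduction reward", {
  ds <- generate_synthetic(n = 40, d = 10, n_informative = 1,
                           effect_size = 2, seed = 5)$data
  expect_equal(subset_fitness(ds, c(rep(1, 5), rep(0, 5)), beta = 0.2, acc = 0.9),
               0.82)
  expect_equal(subset_fitness(ds, rep(1, 10), beta = 0.2, acc = 1), 0.8)

  bits <- c(1, rep(0, 9))
  folds <- make_folds(ds, seed = 1)
  acc <- cv_evaluate(ds, bits, folds = folds, classifier = "surrogate")$means[["accuracy"]]
  expect_identical(subset_fitness(ds, bits, beta = 0, folds = folds,
                                  classifier = "surrogate"), acc)

  # fewer features win at equal accuracy; more accuracy wins at equal size
  expect_gt(subset_fitness(ds, c(1, rep(0, 9)), acc = 0.9),
            subset_fitness(ds, c(1, 1, rep(0, 8)), acc = 0.9))
  expect_gt(subset_fitness(ds, c(1, rep(0, 9)), acc = 0.95),
            subset_fitness(ds, c(1, rep(0, 9)), acc = 0.9))
  expect_error(subset_fitness(ds, rep(0, 10)), "empty")
})

test_that("fitness cache serves repeats without re-evaluating", {
  ds <- generate_synthetic(n = 40, d = 6, n_informative = 2,
                           effect_size = 2, seed = 6)$data
  fn <- ehbcs:::make_fitness(ds, classifier = "surrogate", seed = 1)
  bits <- c(1, 0, 1, 0, 0, 1)
  v1 <- fn(bits); v2 <- fn(bits)
  expect_identical(v1, v2)
  ctr <- attr(fn, "counters")()
  expect_equal(ctr$n_evaluations, 1L)
  expect_equal(ctr$n_cache_hits, 1L)
})

test_that("exhaustive surrogate enumeration of d = 8 stays fast", {
  syn <- generate_synthetic(n = 60, d = 8, n_informative = 2,
                            effect_size = 2, seed = 2)
  folds <- make_folds(syn$data, seed = 2)
  el <- system.time(
    or <- oracle_best_subset(syn$data, folds, classifier = "surrogate")
  )[["elapsed"]]
  expect_lt(el, 5)
  expect_gte(or$fitness, subset_fitness(syn$data, rep(1, 8), folds = folds,
                                        classifier = "surrogate"))
})

test_that("benchmark aggregates runs with the population-sd convention", {
  syn <- generate_synthetic(n = 60, d = 8, n_informative = 2,
                            effect_size = 2, seed = 11)
  b1 <- fs_benchmark(syn$data, algorithms = "bga", runs = 1, n_iter = 3,
                     classifier = "surrogate", seed = 4)
  row <- b1$table[b1$table$Algorithm == "bga", ]
  expect_equal(row$Std, 0)
  expect_equal(row$Max, row$Avgacc)
  expect_equal(row$Min, row$Avgacc)

  b <- fs_benchmark(syn$data, algorithms = c("ehbcs", "bpso"), runs = 2,
                    n_iter = 3, classifier = "surrogate", seed = 4)
  tab <- b$table
  expect_true(all(tab$Min <= tab$Avgacc + 1e-12 & tab$Avgacc <= tab$Max + 1e-12))
  expect_true(all(tab$AvgN <= 8))
  expect_true(all(tab$Std >= 0))
  expect_equal(tab$SizeReduction, (8 - tab$AvgN) / 8 * 100)
  # avg row is the column mean of the algorithm rows
  expect_equal(tab$Avgacc[3], mean(tab$Avgacc[1:2]))
  # population convention: run accuracies (a1, a2) give sd = |a1 - a2| / 2
  accs <- b$runs$accuracy[b$runs$algorithm == "ehbcs"]
  expect_equal(tab$Std[tab$Algorithm == "ehbcs"], abs(diff(accs)) / 2)
})
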
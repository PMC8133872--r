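# The modelling surface: formula interface, methods, serialization, CLI.

make_toy <- function(n = 60, seed = 20) {
  syn <- generate_synthetic(n = n, d = 8, n_informative = 2,
                            effect_size = 2.5, seed = seed)
  syn$data
}

test_that("formula and default interfaces agree", {
  ds <- make_toy()
  df <- as.data.frame(ds$features)
  df$outcome <- factor(ifelse(ds$labels == 1, "case", "control"))
  f1 <- feature_select(outcome ~ ., data = df, algorithm = "ehbcs",
                       n_iter = 5, classifier = "surrogate", seed = 2)
  f2 <- feature_select(df[setdiff(names(df), "outcome")], df$outcome,
                       algorithm = "ehbcs", n_iter = 5,
                       classifier = "surrogate", seed = 2)
  expect_identical(f1$best_bits, f2$best_bits)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_equal(unname(f1$data$label_map), c("case", "control"))
})

test_that("print, summary and coef expose the fit", {
  ds <- make_toy()
  fit <- feature_select(ds, algorithm = "ehbcs", n_iter = 5,
                        classifier = "surrogate", seed = 3)
  expect_output(print(fit), "Feature selection by EHBCS")
  expect_output(print(fit), "fitness")
  expect_output(print(summary(fit)), "Selected features")
  cf <- coef(fit)
  expect_named(cf, ds$feature_names)
  expect_identical(cf, fit$weights$w)

  bga <- feature_select(ds, algorithm = "bga", n_iter = 3,
                        classifier = "surrogate", seed = 3)
  expect_identical(unname(coef(bga)), as.numeric(bga$best_bits))
})

test_that("predict classifies new cases on the original label scale", {
  set.seed(33)
  y <- rep_len(c("a", "b"), 80)
  x <- cbind(sig = ifelse(y == "b", 3, 0) + rnorm(80, sd = 0.3),
             junk = rnorm(80))
  ds <- fs_dataset(x[1:60, ], y[1:60])
  fit <- feature_select(ds, algorithm = "ehbcs", n_iter = 10,
                        classifier = "surrogate", seed = 5,
                        control = list(relief_variant = "nearest"))
  pred <- predict(fit, x[61:80, ])
  expect_s3_class(pred, "factor")
  expect_true(all(levels(pred) %in% c("a", "b")))
  expect_gt(mean(as.character(pred) == y[61:80]), 0.9)

  svm_fit <- feature_select(ds, algorithm = "bga", n_iter = 3,
                            classifier = "svm_rbf", seed = 5)
  pred2 <- predict(svm_fit, x[61:80, ])
  expect_gt(mean(as.character(pred2) == y[61:80]), 0.8)
})

test_that("plot draws a trajectory and warns on empty runs", {
  ds <- make_toy()
  fit <- feature_select(ds, n_iter = 4, classifier = "surrogate", seed = 1)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  empty <- feature_select(ds, n_iter = 0, classifier = "surrogate", seed = 1)
  expect_warning(plot(empty), "no iterations")
})

test_that("run results serialize to JSON with full config echo", {
  ds <- make_toy()
  fit <- feature_select(ds, n_iter = 4, classifier = "surrogate", seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_json(fit, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$algorithm, "ehbcs")
  expect_equal(j$seed, 8)
  expect_equal(unlist(j$selected), fit$selected)
  expect_equal(j$best_fitness, fit$best_fitness)
  expect_length(j$trajectory, 4)
  expect_equal(j$control$p_r, 0.3)
})

run_cli <- function(...) {
  cli <- system.file("scripts", "ehbcs-cli.R", package = "ehbcs")
  rscript <- file.path(R.home("bin"), "Rscript")
  system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE,
          env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
}

test_that("CLI select runs are byte-identical for a fixed seed", {
  skip_if_not_installed("optparse")
  data_csv <- withr::local_tempfile(fileext = ".csv")
  write_dataset(make_toy(n = 40), data_csv)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run <- function(out) {
    run_cli("select", "--data", data_csv, "--algo", "ehbcs",
            "--classifier", "surrogate", "--n-iter", "4", "--seed", "7",
            "--out", out)
  }
  run(out1); run(out2)
  expect_identical(readLines(file.path(out1, "run_result.json")),
                   readLines(file.path(out2, "run_result.json")))
  sel <- read.csv(file.path(out1, "selected_features.csv"))
  expect_true(all(sel$feature %in% paste0("f", 1:8)))
})

test_that("CLI validates its inputs with clean errors", {
  skip_if_not_installed("optparse")
  data_csv <- withr::local_tempfile(fileext = ".csv")
  write_dataset(make_toy(n = 40), data_csv)
  res <- suppressWarnings(
    run_cli("select", "--data", data_csv, "--label", "missing_col"))
  expect_equal(attr(res, "status"), 2)
  expect_true(any(grepl("missing_col", res)))
  res2 <- suppressWarnings(
    run_cli("benchmark", "--data", data_csv, "--algos", ","))
  expect_equal(attr(res2, "status"), 2)
})

test_that("CLI synth writes a dataset with a matching ground-truth sidecar", {
  skip_if_not_installed("optparse")
  out <- withr::local_tempdir()
  run_cli("synth", "--n", "50", "--d", "6", "--informative", "2",
          "--effect", "1.5", "--seed", "3", "--out", out)
  ds <- read_dataset(file.path(out, "synthetic.csv"))
  truth <- jsonlite::read_json(file.path(out, "synthetic_truth.json"))
  expect_equal(ncol(ds$features), 6)
  expect_equal(nrow(ds$features), 50)
  expect_length(truth$informative, truth$n_informative)
  expect_equal(truth$seed, 3)
})
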
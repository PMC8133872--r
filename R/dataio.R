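# Dataset container and I/O: labeled numeric matrices with a binary class
# label, plus normalization, stratified cross-validation folds and a
# planted-signal synthetic generator used throughout the test-bench.

#' Construct a binary-labeled dataset
#'
#' Bundles a numeric feature matrix with a binary class label into the
#' container the selectors operate on. Labels are remapped to `{0, 1}` with
#' the lexicographically smaller original value becoming 0 (unless
#' `positive_label` forces the value mapped to 1); the mapping is recorded so
#' that sensitivity/specificity orientation is auditable.
#'
#' @param features numeric matrix or data frame, cases in rows.
#' @param labels vector with exactly two distinct values, length `nrow(features)`.
#' @param feature_names optional character vector of unique feature names;
#'   defaults to column names or `f1..fd`.
#' @param case_ids optional character vector of case identifiers.
#' @param positive_label original label value to map to 1 (the "positive"
#'   class for sensitivity/precision). Default: the lexicographically larger
#'   value.
#' @return An object of class `fs_dataset`: a list with elements `features`
#'   (n x d numeric matrix), `labels` (integer 0/1), `feature_names`,
#'   `case_ids` and `label_map` (original values for 0 and 1).
#' @export
fs_dataset <- function(features, labels, feature_names = NULL, case_ids = NULL,
                       positive_label = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  if (n < 2L) stop("need at least 2 cases")
  if (d < 1L) stop("need at least 1 feature")
  if (length(labels) != n) stop("labels length must match number of cases")
  if (anyNA(features) || anyNA(labels)) stop("missing values are not supported; impute or drop first")
  if (!all(is.finite(features))) stop("non-finite feature values")

  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("not a binary-label dataset (found ", length(lev), " classes)")
  num <- suppressWarnings(as.numeric(lev))
  # numeric labels (incl. -1/+1) ordered numerically; otherwise a
  # locale-independent lexicographic order
  lev <- if (!anyNA(num)) lev[order(num)] else sort(lev, method = "radix")
  if (!is.null(positive_label)) {
    positive_label <- as.character(positive_label)
    if (!positive_label %in% lev) stop("positive_label ", positive_label, " not present in labels")
    lev <- c(setdiff(lev, positive_label), positive_label)
  }
  y <- as.integer(as.character(labels) == lev[2L])

  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d))
  feature_names <- as.character(feature_names)
  blank <- is.na(feature_names) | feature_names == ""
  feature_names[blank] <- paste0("f", which(blank))
  if (length(feature_names) != d) stop("feature_names length must match feature count")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  if (is.null(case_ids)) case_ids <- rownames(features)
  if (is.null(case_ids)) case_ids <- paste0("case", seq_len(n))
  colnames(features) <- feature_names
  rownames(features) <- NULL

  structure(
    list(features = features, labels = y, feature_names = feature_names,
         case_ids = as.character(case_ids),
         label_map = c("0" = lev[1L], "1" = lev[2L])),
    class = "fs_dataset")
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat("Binary-labeled dataset: ", nrow(x$features), " cases x ",
      ncol(x$features), " features\n", sep = "")
  tab <- table(x$labels)
  cat("  class 0 ('", x$label_map[["0"]], "'): ", tab[["0"]],
      " | class 1 ('", x$label_map[["1"]], "'): ", tab[["1"]], "\n", sep = "")
  invisible(x)
}

#' Read a labeled dataset from CSV or LIBSVM/SVMlight format
#'
#' CSV files need a header row; the label column is named (or indexed) by
#' `label_column` and every other column must be numeric. LIBSVM files use
#' the sparse `label idx:value ...` lines with 1-based feature indices;
#' absent entries are 0.
#'
#' @param path file path.
#' @param format `"csv"` or `"libsvm"`.
#' @param label_column CSV only: column name or index holding the class label.
#' @param positive_label passed to [fs_dataset()].
#' @return An [fs_dataset()] with row order preserved.
#' @export
read_dataset <- function(path, format = c("csv", "libsvm"), label_column = "label",
                         positive_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (is.character(label_column)) {
      if (!label_column %in% names(df)) stop("label column '", label_column, "' not found in ", path)
      li <- match(label_column, names(df))
    } else {
      li <- as.integer(label_column)
      if (li < 1L || li > ncol(df)) stop("label column index out of range")
    }
    labels <- df[[li]]
    feats <- df[-li]
    bad <- !vapply(feats, is.numeric, logical(1))
    if (any(bad)) {
      j <- which(bad)[1L]
      r <- which(is.na(suppressWarnings(as.numeric(feats[[j]]))))[1L]
      stop("non-numeric feature value in column '", names(feats)[j],
           "', row ", ifelse(is.na(r), "?", r))
    }
    fs_dataset(as.matrix(feats), labels, feature_names = names(feats),
               positive_label = positive_label)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    labels <- vapply(toks, function(t) t[[1L]], character(1))
    pairs <- lapply(toks, function(t) {
      if (length(t) < 2L) return(matrix(numeric(0), ncol = 2L))
      kv <- strsplit(t[-1L], ":", fixed = TRUE)
      m <- matrix(as.numeric(unlist(kv)), ncol = 2L, byrow = TRUE)
      if (anyNA(m)) stop("malformed index:value pair in ", path)
      m
    })
    d <- max(1, vapply(pairs, function(m) if (nrow(m)) max(m[, 1L]) else 0, numeric(1)))
    x <- matrix(0, nrow = length(lines), ncol = d)
    for (i in seq_along(pairs)) {
      m <- pairs[[i]]
      if (nrow(m)) x[i, m[, 1L]] <- m[, 2L]
    }
    fs_dataset(x, labels, positive_label = positive_label)
  }
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()] for the CSV format: features plus a final
#' `label` column carrying the original label values.
#'
#' @param data an [fs_dataset()].
#' @param path output file path.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "fs_dataset"))
  df <- as.data.frame(data$features, check.names = FALSE)
  df$label <- data$label_map[as.character(data$labels)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize features
#'
#' `minmax` affinely maps each feature to `[0, 1]` (constant features map to
#' 0); `zscore` centers and scales (constant features map to 0); `none`
#' returns the data unchanged. The per-feature scale parameters are kept in
#' the `"scaling"` attribute. Min-max scaling is the conventional
#' preprocessing for Relief, whose weights accumulate raw absolute
#' differences and are therefore scale-sensitive.
#'
#' @param data an [fs_dataset()].
#' @param method `"minmax"`, `"zscore"` or `"none"`.
#' @return The dataset with transformed features.
#' @export
normalize_features <- function(data, method = c("minmax", "zscore", "none")) {
  stopifnot(inherits(data, "fs_dataset"))
  method <- match.arg(method)
  if (method == "none") return(data)
  x <- data$features
  if (method == "minmax") {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    rng <- hi - lo
    const <- rng == 0
    rng[const] <- 1
    x <- sweep(sweep(x, 2L, lo, "-"), 2L, rng, "/")
    x[, const] <- 0
    scaling <- list(method = "minmax", min = lo, range = hi - lo)
  } else {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    const <- sdv == 0
    sdv[const] <- 1
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
    x[, const] <- 0
    scaling <- list(method = "zscore", mean = mu, sd = sdv)
  }
  colnames(x) <- data$feature_names
  data$features <- x
  attr(data, "scaling") <- scaling
  data
}

#' Build stratified cross-validation folds
#'
#' Fold count follows the protocol rule: 5 folds for datasets with fewer than
#' 100 cases, 10 otherwise, unless overridden. Folds are stratified: within
#' each class, cases are shuffled and dealt round-robin, so every fold's
#' label proportion is within one case of the global proportion.
#'
#' @param data an [fs_dataset()].
#' @param k optional fold-count override.
#' @param seed integer seed; assignments are deterministic given it.
#' @return An object of class `fold_plan`: list with `k` and `assignments`
#'   (length-n integer fold index in `1..k`).
#' @export
make_folds <- function(data, k = NULL, seed = 1L) {
  stopifnot(inherits(data, "fs_dataset"))
  n <- nrow(data$features)
  if (is.null(k)) k <- if (n < 100L) 5L else 10L
  k <- as.integer(k)
  cls_sizes <- table(data$labels)
  if (k > min(cls_sizes)) stop("insufficient cases for stratified folds (k = ", k,
                               ", smallest class = ", min(cls_sizes), ")")
  assignments <- integer(n)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(data$labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, assignments = assignments), class = "fold_plan")
}

#' Generate a synthetic binary-classification dataset with planted signal
#'
#' Informative features are class-conditional Gaussians with unit variance
#' and a standardized between-class mean shift of `effect_size`; noise
#' features are standard normal in both classes; redundant features copy an
#' informative feature (cycled) plus `N(0, noise_sd^2)` noise. Class sizes
#' are fixed at `round(n * class_balance)` positives, and case order is
#' shuffled. Everything is reproducible from `seed`.
#'
#' @param n,d cases and features.
#' @param n_informative number of signal-carrying features (first indices).
#' @param effect_size standardized class mean shift per informative feature
#'   (>= 0; 0 gives a pure-null dataset).
#' @param n_redundant features duplicated (plus noise) from informative ones.
#' @param noise_sd standard deviation of the noise added to redundant copies.
#' @param class_balance proportion of positive (label 1) cases, in (0, 1).
#' @param seed integer seed.
#' @return List with `data` (an [fs_dataset()]), `informative` and
#'   `redundant` (integer index vectors into the feature columns).
#' @export
generate_synthetic <- function(n, d, n_informative, effect_size = 1,
                               n_redundant = 0L, noise_sd = 0.1,
                               class_balance = 0.5, seed = 1L) {
  stopifnot(n >= 4, d >= 1, n_informative >= 0, effect_size >= 0,
            n_informative + n_redundant <= d,
            class_balance > 0, class_balance < 1)
  with_seed(seed, {
    n1 <- max(2L, min(n - 2L, round(n * class_balance)))
    y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    x <- matrix(stats::rnorm(n * d), n, d)
    if (n_informative > 0) {
      for (j in seq_len(n_informative)) {
        x[y == 1L, j] <- x[y == 1L, j] + effect_size
      }
    }
    redundant <- integer(0)
    if (n_redundant > 0) {
      if (n_informative < 1L) stop("redundant features require informative ones")
      redundant <- n_informative + seq_len(n_redundant)
      src <- rep_len(seq_len(n_informative), n_redundant)
      for (i in seq_len(n_redundant)) {
        x[, redundant[i]] <- x[, src[i]] + stats::rnorm(n, 0, noise_sd)
      }
    }
    list(data = fs_dataset(x, y, feature_names = paste0("f", seq_len(d))),
         informative = seq_len(n_informative), redundant = redundant)
  })
}
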
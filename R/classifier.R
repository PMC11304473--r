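#' Published methane emission-level boundary presets
#'
#' Two printed four-boundary sets delimiting five seasonal CH4 levels
#' (kg ha^-1) are in circulation for this analysis: the discretization cuts
#' 56.6/129/207/317 and the classification-tree legend cuts 73.6/162/254/383.
#' Both ship as named presets for replaying fixed-boundary discretization;
#' neither is endorsed over the other.
#'
#' @param preset `"pooled"` (56.6, 129, 207, 317) or `"tree"`
#'   (73.6, 162, 254, 383).
#' @return Ascending numeric boundaries of length 4.
#' @export
level_boundaries_preset <- function(preset = c("pooled", "tree")) {
  preset <- match.arg(preset)
  switch(preset,
    pooled = c(56.6, 129, 207, 317),
    tree = c(73.6, 162, 254, 383)
  )
}

#' Discretize seasonal CH4 totals into emission levels
#'
#' Equal-frequency mode places cut points at the i/n quantiles (i = 1..n-1)
#' of the supplied values; fixed mode uses user-supplied boundaries (e.g. a
#' [level_boundaries_preset()]). Intervals are left-open right-closed except
#' the lowest, so a value equal to a boundary belongs to the lower level.
#'
#' @param values Seasonal CH4 totals (kg ha^-1).
#' @param n_levels Number of levels (default 5).
#' @param method `"equal_frequency"` (default) or `"fixed"`.
#' @param boundaries Ascending cut points (required for `"fixed"`).
#' @return A list with `scheme` (list `n_levels`, `boundaries`, `method`) and
#'   `levels` (integer labels 1..n, parallel to `values`).
#' @export
discretize_levels <- function(values, n_levels = 5,
                              method = c("equal_frequency", "fixed"),
                              boundaries = NULL) {
  method <- match.arg(method)
  if (method == "equal_frequency") {
    if (length(unique(values)) < n_levels) {
      abort("too few distinct values for equal-frequency discretization")
    }
    boundaries <- unname(quantile(values, seq_len(n_levels - 1) / n_levels))
    if (any(duplicated(boundaries))) {
      abort("tied quantiles: too few distinct values for equal-frequency levels")
    }
  } else {
    if (is.null(boundaries)) abort("fixed discretization needs boundaries")
    n_levels <- length(boundaries) + 1L
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("boundaries must be strictly increasing")
  }
  lv <- findInterval(values, boundaries, left.open = TRUE) + 1L
  list(
    scheme = list(n_levels = as.integer(n_levels), boundaries = boundaries,
                  method = method),
    levels = lv
  )
}

#' Stratified train/test split
#'
#' Splits record indices into train and test sets preserving the level
#' proportions: within each level, `floor(n * ratio + 0.5)` records go to
#' training after a seeded shuffle. The two sets are disjoint and exhaustive.
#'
#' @param labels Level labels, one per record.
#' @param ratio Training fraction, in (0, 1). Default 0.8.
#' @param seed Integer RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    abort("split ratio must lie strictly between 0 and 1")
  }
  sizes <- table(labels)
  if (any(sizes < 2)) {
    abort(paste0("level(s) with a single member: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train <- integer()
  for (lv in names(sizes)) {
    idx <- sample(which(labels == lv))
    n_tr <- floor(length(idx) * ratio + 0.5)
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Fit the emission-level random forest and classification tree
#'
#' Fits (i) a random forest (default 500 trees, sqrt(p) descriptors tried per
#' split) reporting the out-of-bag error and per-descriptor Gini importance,
#' and (ii) a single interpretable classification tree grown with a minimum
#' leaf size and pruned by the 1-SE cost-complexity rule under seeded internal
#' cross-validation. Both are evaluated on the held-out stratified test set.
#'
#' @param descriptors Descriptor tibble (`field_id` + the 17 descriptors).
#' @param levels Integer emission levels, parallel to `descriptors` rows.
#' @param split_ratio Training fraction (default 0.8).
#' @param seed Integer RNG seed (split, forest bootstrap, tree
#'   cross-validation).
#' @param n_trees Forest size (default 500).
#' @param min_leaf Minimum tree leaf size (default 5).
#' @return A `paddy_classifier`: `forest`, `tree`, `oob_error`,
#'   `gini_importance` (tibble), `split`, `test_confusion`, `test_accuracy`,
#'   `n_train`, `n_test`.
#' @export
fit_level_classifier <- function(descriptors, levels, split_ratio = 0.8,
                                 seed = 1L, n_trees = 500, min_leaf = 5) {
  if (!all(DESCRIPTOR_NAMES %in% names(descriptors))) {
    abort("descriptor table must contain A1..A8, B1..B6, C1..C3")
  }
  y <- factor(levels)
  if (nlevels(y) < 2) abort("training labels are a single class")
  split <- stratified_split(levels, ratio = split_ratio, seed = seed)
  if (length(split$train) < 30) abort("need at least 30 training records")
  x <- as.data.frame(descriptors[, DESCRIPTOR_NAMES])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x[split$train, ], y = y[split$train],
    ntree = n_trees, mtry = floor(sqrt(length(DESCRIPTOR_NAMES)))
  )
  oob <- unname(forest$err.rate[n_trees, "OOB"])
  gini <- tibble::tibble(
    descriptor = rownames(forest$importance),
    gini_importance = forest$importance[, "MeanDecreaseGini"]
  ) |>
    dplyr::arrange(dplyr::desc(.data$gini_importance))

  train_df <- cbind(.level = y[split$train], x[split$train, ])
  set.seed(seed + 1L)
  tree <- rpart::rpart(
    .level ~ ., data = train_df, method = "class",
    control = rpart::rpart.control(minbucket = min_leaf, cp = 0, xval = 10)
  )
  cp <- tree$cptable
  i_min <- which.min(cp[, "xerror"])
  thresh <- cp[i_min, "xerror"] + cp[i_min, "xstd"]
  i_1se <- which(cp[, "xerror"] <= thresh)[1]
  tree <- rpart::prune(tree, cp = cp[i_1se, "CP"])

  test_x <- x[split$test, , drop = FALSE]
  pred <- if (nrow(test_x)) predict(forest, test_x) else factor(levels(y))[0]
  conf <- table(observed = y[split$test], predicted = pred)
  structure(
    list(
      forest = forest, tree = tree, oob_error = oob, gini_importance = gini,
      split = split, test_confusion = conf,
      test_accuracy = if (nrow(test_x)) mean(pred == y[split$test]) else NA_real_,
      n_train = length(split$train), n_test = length(split$test)
    ),
    class = "paddy_classifier"
  )
}

#' @export
print.paddy_classifier <- function(x, ...) {
  cat("<paddy_classifier>", x$n_train, "train /", x$n_test, "test records\n")
  cat("  forest OOB error:", round(100 * x$oob_error, 1), "%",
      "  held-out accuracy:", round(100 * x$test_accuracy, 1), "%\n")
  cat("  top descriptors:",
      paste(head(x$gini_importance$descriptor, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Predict emission levels for new fields
#'
#' @param model A `paddy_classifier`.
#' @param descriptors Descriptor tibble with `field_id` and all 17
#'   descriptors (missing descriptors are an error).
#' @return Tibble `field_id`, `forest` and `tree` predicted levels (integer).
#' @export
predict_level <- function(model, descriptors) {
  stopifnot(inherits(model, "paddy_classifier"))
  miss <- setdiff(DESCRIPTOR_NAMES, names(descriptors))
  if (length(miss)) {
    abort(paste0("missing descriptor(s): ", paste(miss, collapse = ", ")))
  }
  x <- as.data.frame(descriptors[, DESCRIPTOR_NAMES])
  if (anyNA(x)) abort("missing descriptor values")
  tibble::tibble(
    field_id = descriptors$field_id,
    forest = as.integer(as.character(predict(model$forest, x))),
    tree = as.integer(as.character(
      predict(model$tree, x, type = "class")
    ))
  )
}
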
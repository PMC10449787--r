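#' Stratified train/test split of a labeled feature table
#'
#' Splits the rows 70:30 (by default) into disjoint, exhaustive train and
#' test sets, stratified by class label. The total training size is
#' `round(ratio * n)`; per-class allocations are rounded and then adjusted
#' so the total matches and both classes appear in both parts.
#'
#' @param table Labeled feature table (no `NA` labels).
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with `train` and `test` feature tibbles and
#'   `split_record` (tibble `contig_id`, `part`).
#' @export
split_train_test <- function(table, ratio = 0.7, seed) {
  stopifnot(!missing(seed), ratio > 0, ratio < 1)
  if (anyNA(table$label)) abort("All rows must be labeled for splitting")
  counts <- table(table$label)
  if (any(counts < 5L)) {
    abort(paste0("Class(es) with fewer than 5 members cannot be ",
                 "stratified for five-fold work downstream: ",
                 paste(names(counts)[counts < 5L], collapse = ", ")))
  }
  n <- nrow(table)
  target <- round(ratio * n)
  classes <- names(counts)
  n_train <- setNames(as.integer(round(ratio * as.integer(counts))),
                      classes)
  # keep both parts non-empty per class, then reconcile to the total
  n_train <- pmin(pmax(n_train, 1L), as.integer(counts) - 1L)
  while (sum(n_train) > target) {
    i <- which.max(n_train)
    n_train[i] <- n_train[i] - 1L
  }
  while (sum(n_train) < target) {
    room <- as.integer(counts) - 1L - n_train
    i <- which.max(room)
    n_train[i] <- n_train[i] + 1L
  }
  set.seed(seed)
  train_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(table$label == cl)
    sample(idx, n_train[cl])
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  rec <- tibble(contig_id = table$contig_id,
                part = ifelse(seq_len(n) %in% train_idx, "train", "test"))
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE],
       split_record = rec)
}

av_feature_cols <- function(table) {
  setdiff(names(table), c("contig_id", "label"))
}

as_label_factor <- function(label) {
  factor(label, levels = c(av_positive_class, "phage"))
}

#' Train the random-forest classifier
#'
#' Fits a seeded random forest on a labeled feature table. Gini importances
#' (mean decrease in node impurity, normalized to sum to 1) and the
#' out-of-bag error estimate are recorded with the model, together with the
#' feature catalog version so that prediction refuses tables built under a
#' different catalog.
#'
#' @param train Labeled feature table.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed (mandatory; identical seeds give identical
#'   forests and predictions).
#' @param features Optional character vector restricting the columns used
#'   (e.g. an RFE-selected set); default all feature columns.
#' @return An object of class `av_model`.
#' @export
train_forest <- function(train, n_trees = 1000L, seed, features = NULL) {
  stopifnot(!missing(seed))
  if (anyNA(train$label)) abort("All training rows must be labeled")
  if (length(unique(train$label)) < 2L) {
    abort("Training data must contain both classes")
  }
  features <- features %||% av_feature_cols(train)
  missing_cols <- setdiff(features, names(train))
  if (length(missing_cols)) {
    abort(paste0("Feature column(s) absent from table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(train[, features, drop = FALSE])
  y <- as_label_factor(train$label)
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                       importance = FALSE)
  imp <- forest$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  gini <- if (total > 0) imp / total else imp
  structure(list(
    forest = forest,
    feature_names = features,
    known_columns = union(features, feature_catalog()),
    gini_importances = setNames(as.numeric(gini), features),
    n_trees = n_trees,
    seed = seed,
    oob_error = unname(forest$err.rate[n_trees, "OOB"]),
    class_counts = table(train$label),
    catalog_version = attr(train, "catalog_version") %||%
      attr(feature_catalog(), "version"),
    rfe_trace = NULL,
    split_record = NULL
  ), class = "av_model")
}

#' @export
print.av_model <- function(x, ...) {
  cat("Random-forest archaeal-virus classifier\n")
  cat("  trees:", x$n_trees, " seed:", x$seed, "\n")
  cat("  features:", length(x$feature_names), "\n")
  cat("  OOB error:", signif(x$oob_error, 3), "\n")
  cat("  training class counts:",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# F1 for the archaeal-virus positive class; 0 when no true or predicted
# positives exist on either side of the harmonic mean.
f1_score <- function(truth, predicted) {
  tp <- sum(truth == av_positive_class & predicted == av_positive_class)
  fp <- sum(truth != av_positive_class & predicted == av_positive_class)
  fn <- sum(truth == av_positive_class & predicted != av_positive_class)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Predict archaeal-virus probabilities for contigs
#'
#' The probability is the fraction of trees voting for the archaeal-virus
#' class; a contig is classed archaeal when its probability is at or above
#' the threshold (so at an exact 50:50 tree split the archaeal call is
#' made only for thresholds of 0.5 or below). The recommended threshold
#' for confident calls is 0.80.
#'
#' @param model An `av_model`.
#' @param table Feature table containing at least the model's features.
#' @param threshold Decision threshold on the archaeal vote fraction.
#' @return A tibble `contig_id`, `p_archaeal`, `p_phage`,
#'   `predicted_class`, `threshold_used`.
#' @export
predict_contigs <- function(model, table, threshold = 0.8) {
  stopifnot(inherits(model, "av_model"), threshold >= 0, threshold <= 1)
  tab_version <- attr(table, "catalog_version")
  if (!is.null(tab_version) && !is.na(tab_version) &&
      !identical(tab_version, model$catalog_version)) {
    abort(paste0("Feature catalog mismatch: model was trained under '",
                 model$catalog_version, "', table was built under '",
                 tab_version, "'"))
  }
  missing_cols <- setdiff(model$feature_names, names(table))
  if (length(missing_cols)) {
    abort(paste0("Feature column(s) required by the model are missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(av_feature_cols(table), model$known_columns)
  if (length(extra)) {
    warn(paste0("Ignoring column(s) unknown to the model: ",
                paste(extra, collapse = ", ")))
  }
  x <- as.data.frame(table[, model$feature_names, drop = FALSE])
  votes <- predict(model$forest, newdata = x, type = "vote",
                   norm.votes = TRUE)
  p <- as.numeric(votes[, av_positive_class])
  tibble(contig_id = table$contig_id,
         p_archaeal = p,
         p_phage = as.numeric(votes[, "phage"]),
         predicted_class = ifelse(p >= threshold, av_positive_class,
                                  "phage"),
         threshold_used = threshold)
}

# Deterministic stratified k-fold assignment.
stratified_folds <- function(label, k, seed) {
  set.seed(seed)
  fold <- integer(length(label))
  for (cl in unique(label)) {
    idx <- which(label == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Recursive feature elimination by Gini importance
#'
#' Starting from all feature columns, repeatedly (i) scores the current
#' set by stratified five-fold cross-validated F1 and (ii) removes the
#' feature with the lowest mean Gini importance across the fold forests,
#' down to a floor of `min_features`. The selected set is the step with
#' the highest cross-validated F1; ties go to the smaller set.
#'
#' @param table Labeled feature table.
#' @param folds Number of CV folds (default 5).
#' @param min_features Minimum retained features (default 5).
#' @param seed Integer seed.
#' @param n_trees Trees per fold forest.
#' @return An object of class `av_rfe`: list with `trace` (tibble `step`,
#'   `n_features`, `cv_f1`, `features` list-column), `selected` (character
#'   vector) and `best_step`.
#' @export
rfe_select <- function(table, folds = 5L, min_features = 5L, seed,
                       n_trees = 200L) {
  stopifnot(!missing(seed))
  feats <- av_feature_cols(table)
  if (length(feats) < min_features) {
    abort(paste0("Table has ", length(feats), " feature columns; at least ",
                 min_features, " required"))
  }
  fold <- stratified_folds(table$label, folds, seed)
  trace <- list()
  step <- 0L
  current <- feats
  repeat {
    step <- step + 1L
    f1s <- numeric(folds)
    gini_sum <- setNames(numeric(length(current)), current)
    for (k in seq_len(folds)) {
      tr <- table[fold != k, , drop = FALSE]
      te <- table[fold == k, , drop = FALSE]
      m <- train_forest(tr, n_trees = n_trees, seed = seed + 1000L * k,
                        features = current)
      pred <- predict_contigs(m, te[, c("contig_id", current, "label")],
                              threshold = 0.5)
      f1s[k] <- f1_score(te$label, pred$predicted_class)
      gini_sum <- gini_sum + m$gini_importances[current]
    }
    trace[[step]] <- tibble(step = step, n_features = length(current),
                            cv_f1 = mean(f1s), features = list(current))
    if (length(current) <= min_features) break
    drop_feat <- names(which.min(gini_sum))
    current <- setdiff(current, drop_feat)
  }
  trace <- dplyr::bind_rows(trace)
  # highest F1 wins; among ties, the smaller feature set (larger step)
  best <- trace |>
    dplyr::filter(.data$cv_f1 == max(.data$cv_f1)) |>
    dplyr::slice_max(.data$step, n = 1)
  structure(list(trace = trace, selected = best$features[[1]],
                 best_step = best$step), class = "av_rfe")
}

#' @export
print.av_rfe <- function(x, ...) {
  cat("Recursive feature elimination trace (", nrow(x$trace),
      " steps)\n", sep = "")
  cat("  selected ", length(x$selected), " features at step ",
      x$best_step, " (CV F1 = ",
      signif(x$trace$cv_f1[x$trace$step == x$best_step], 3), ")\n",
      sep = "")
  invisible(x)
}

#' Fit the full classifier pipeline on a labeled feature table
#'
#' Convenience wrapper chaining correlation pruning, recursive feature
#' elimination, the stratified 70:30 split, and the final forest fit on
#' the training portion with the selected features. Held-out performance
#' on the 30% test portion is recorded in the model.
#'
#' @param table Labeled feature table (all 27 catalog columns).
#' @param seed Integer seed governing every random choice.
#' @param n_trees Trees in the final forest.
#' @param ratio Training fraction of the split.
#' @param folds,min_features RFE settings (see [rfe_select()]).
#' @param r_max Correlation-pruning ceiling; `NULL` skips pruning.
#' @param rfe If `FALSE`, skip feature elimination and use all surviving
#'   columns.
#' @param rfe_trees Trees per RFE fold forest.
#' @return An `av_model` with `rfe_trace`, `split_record`, `pruned` (the
#'   removal log) and `test_metrics` populated.
#' @export
train_classifier <- function(table, seed, n_trees = 1000L, ratio = 0.7,
                             folds = 5L, min_features = 5L, r_max = 0.95,
                             rfe = TRUE, rfe_trees = 200L) {
  stopifnot(!missing(seed))
  pruned_log <- NULL
  if (!is.null(r_max)) {
    pr <- prune_correlated(table, r_max = r_max)
    table <- pr$table
    pruned_log <- pr$removed
  }
  parts <- split_train_test(table, ratio = ratio, seed = seed)
  rfe_res <- NULL
  features <- av_feature_cols(table)
  if (rfe && length(features) > min_features) {
    rfe_res <- rfe_select(parts$train, folds = folds,
                          min_features = min_features, seed = seed,
                          n_trees = rfe_trees)
    features <- rfe_res$selected
  }
  model <- train_forest(parts$train, n_trees = n_trees, seed = seed,
                        features = features)
  model$rfe_trace <- if (!is.null(rfe_res)) rfe_res$trace else NULL
  model$split_record <- parts$split_record
  model$pruned <- pruned_log
  pred <- predict_contigs(model,
                          parts$test[, c("contig_id", features, "label")],
                          threshold = 0.5)
  cc <- confusion_counts(parts$test$label, pred$predicted_class)
  model$test_metrics <- compute_metrics(cc) |>
    dplyr::mutate(F1 = f1_score(parts$test$label, pred$predicted_class))
  model
}

#' Flag training sequences whose forest proximity contradicts their label
#'
#' The proximity of two rows is the fraction of trees in which they fall
#' into the same terminal leaf. Rows are clustered by average-linkage
#' hierarchical clustering on 1 - proximity and cut into two clusters;
#' each cluster is assigned the majority label of its members, and rows
#' whose own label disagrees with their cluster's majority are reported as
#' outliers (candidate mislabeled or poorly represented sequences).
#'
#' @param model An `av_model`.
#' @param table Labeled feature table with at least 3 rows.
#' @return A list of class `av_proximity`: `matrix` (n x n, symmetric,
#'   unit diagonal), `linkage` (an `hclust`), `clusters` (integer vector),
#'   `outliers` (tibble `contig_id`, `label`, `cluster`,
#'   `cluster_majority`).
#' @export
proximity_outliers <- function(model, table) {
  stopifnot(inherits(model, "av_model"))
  if (nrow(table) < 3L) abort("Need at least 3 rows for proximity clustering")
  if (anyNA(table$label)) abort("All rows must be labeled")
  x <- as.data.frame(table[, model$feature_names, drop = FALSE])
  pr <- predict(model$forest, newdata = x, proximity = TRUE)$proximity
  dimnames(pr) <- list(table$contig_id, table$contig_id)
  hc <- hclust(as.dist(1 - pr), method = "average")
  cl <- cutree(hc, k = 2L)
  majority <- tapply(table$label, cl, function(l)
    names(sort(table(l), decreasing = TRUE))[1])
  res <- tibble(contig_id = table$contig_id, label = table$label,
                cluster = as.integer(cl),
                cluster_majority = unname(majority[as.character(cl)]))
  structure(list(matrix = pr, linkage = hc,
                 clusters = setNames(as.integer(cl), table$contig_id),
                 outliers = dplyr::filter(res,
                                          .data$label != .data$cluster_majority)),
            class = "av_proximity")
}

#' Persist and restore a trained classifier
#'
#' The saved archive contains the forest, the feature catalog version and
#' names, the seed, tree count, RFE trace and split record, so that a
#' loaded model reproduces its predictions exactly. Loading refuses a
#' model trained under a different feature catalog version.
#'
#' @param model An `av_model`.
#' @param path File path for the model archive.
#' @param catalog_version Expected catalog version (default: the current
#'   package catalog). Pass `NULL` to skip the check.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `av_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "av_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path,
                       catalog_version = attr(feature_catalog(), "version")) {
  model <- readRDS(path)
  if (!inherits(model, "av_model")) {
    abort(paste0(path, " does not contain a saved classifier"))
  }
  if (!is.null(catalog_version) &&
      !identical(model$catalog_version, catalog_version)) {
    abort(paste0("Refusing model trained under feature catalog '",
                 model$catalog_version, "'; expected '",
                 catalog_version, "'"))
  }
  model
}
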
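#' Tidy a trained classifier into its feature importances
#'
#' @param x An `av_model`.
#' @param ... Unused.
#' @return A tibble `feature`, `gini_importance` (normalized to sum to 1),
#'   sorted by decreasing importance.
#' @export
tidy.av_model <- function(x, ...) {
  tibble(feature = names(x$gini_importances),
         gini_importance = as.numeric(x$gini_importances)) |>
    dplyr::arrange(dplyr::desc(.data$gini_importance))
}

#' One-row model summary
#'
#' @param x An `av_model`.
#' @param ... Unused.
#' @return A one-row tibble with tree count, feature count, seed, OOB
#'   error and (when the model was fitted via [train_classifier()]) the
#'   held-out test metrics.
#' @export
glance.av_model <- function(x, ...) {
  base <- tibble(n_trees = x$n_trees,
                 n_features = length(x$feature_names),
                 seed = x$seed, oob_error = x$oob_error)
  if (!is.null(x$test_metrics)) {
    base <- dplyr::bind_cols(base,
                             dplyr::rename_with(x$test_metrics,
                                                ~ paste0("test_", .x)))
  }
  base
}

#' Augment a feature table with model predictions
#'
#' @param x An `av_model`.
#' @param data A feature table.
#' @param threshold Decision threshold (default 0.8).
#' @param ... Unused.
#' @return `data` with `.p_archaeal` and `.predicted_class` appended.
#' @export
augment.av_model <- function(x, data, threshold = 0.8, ...) {
  pred <- predict_contigs(x, data, threshold = threshold)
  data$.p_archaeal <- pred$p_archaeal
  data$.predicted_class <- pred$predicted_class
  data
}

#' Tidy a feature-elimination trace
#'
#' @param x An `av_rfe`.
#' @param ... Unused.
#' @return The trace tibble (`step`, `n_features`, `cv_f1`) without the
#'   feature list-column.
#' @export
tidy.av_rfe <- function(x, ...) {
  dplyr::select(x$trace, -"features")
}

#' Tidy ROC/PR curve points
#'
#' @param x An `av_curve`.
#' @param ... Unused.
#' @return The threshold-step tibble.
#' @export
tidy.av_curve <- function(x, ...) x$points

#' One-row curve summary
#'
#' @param x An `av_curve`.
#' @param ... Unused.
#' @return Tibble with `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
glance.av_curve <- function(x, ...) {
  tibble(auroc = x$auroc, auprc = x$auprc, n_pos = x$n_pos,
         n_neg = x$n_neg)
}
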
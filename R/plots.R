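#' Plot ROC and precision-recall curves
#'
#' @param object An `av_curve` from [roc_pr()].
#' @param which `"roc"`, `"pr"` or `"both"` (side by side via facets).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.av_curve <- function(object, which = c("both", "roc", "pr"),
                              ...) {
  which <- match.arg(which)
  pts <- object$points
  roc_df <- dplyr::transmute(pts, x = .data$FPR, y = .data$TPR,
                             panel = sprintf("ROC (AUROC = %.3f)",
                                             object$auroc))
  pr_df <- pts |>
    dplyr::filter(!is.na(.data$precision)) |>
    dplyr::transmute(x = .data$TPR, y = .data$precision,
                     panel = sprintf("PR (AUPRC = %.3f)", object$auprc))
  df <- switch(which, roc = roc_df, pr = pr_df,
               both = dplyr::bind_rows(roc_df, pr_df))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "FPR (ROC) / sensitivity (PR)",
                  y = "TPR (ROC) / precision (PR)") +
    ggplot2::theme_minimal()
}

#' Plot normalized Gini feature importances
#'
#' @param model An `av_model`.
#' @param top_n How many features to show.
#' @return A ggplot object.
#' @export
plot_importance <- function(model, top_n = 20L) {
  df <- tidy(model) |> dplyr::slice_head(n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(.data$gini_importance,
                                   stats::reorder(.data$feature,
                                                  .data$gini_importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Gini importance (normalized)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a feature-elimination trace
#'
#' Cross-validated F1 against the number of retained features, marking
#' the selected step.
#'
#' @param rfe An `av_rfe` from [rfe_select()], or an `av_model` carrying
#'   an `rfe_trace`.
#' @return A ggplot object.
#' @export
plot_rfe_trace <- function(rfe) {
  trace <- if (inherits(rfe, "av_rfe")) rfe$trace else rfe$rfe_trace
  if (is.null(trace)) abort("No feature-elimination trace available")
  best <- trace[which.max(trace$cv_f1), ]
  ggplot2::ggplot(trace, ggplot2::aes(.data$n_features, .data$cv_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = best, colour = "red", size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Features retained", y = "Cross-validated F1") +
    ggplot2::theme_minimal()
}

#' Plot perturbation-benchmark metrics
#'
#' One panel per perturbation type, metric trajectories against the
#' perturbation parameter, split by decision threshold.
#'
#' @param results Tibble from [run_benchmark()].
#' @param metrics Which metric columns to draw.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, metrics = c("TPR", "SPEC", "ACC",
                                                "MCC", "FDR")) {
  df <- results |>
    dplyr::filter(.data$variant != "original") |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(parameter = ifelse(is.infinite(.data$parameter),
                                     NA_real_, .data$parameter))
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(threshold ~ variant, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Perturbation parameter", y = "Metric value") +
    ggplot2::theme_minimal()
}
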
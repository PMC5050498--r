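# ggplot2 views of the pipeline's result types.

#' Plot an ROC curve
#'
#' @param object An [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot: the ROC curve with the chance diagonal and the AUC and
#'   its 95% CI in the subtitle.
#' @export
autoplot.nqi_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = "ROC curve",
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc,
                         object$ci95[1], object$ci95[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot cross-dataset subject scores by group
#'
#' @param object A [cross_dataset_validate()] result.
#' @param ... Unused.
#' @return A ggplot: per-subject nQi scores by diagnostic group and fold.
#' @export
autoplot.nqi_crossval <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$group, y = .data$nqi,
                               colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7, size = 1.6) +
    ggplot2::facet_wrap(~dataset,
                        labeller = ggplot2::as_labeller(
                          c(A = "fold A (trained on B)",
                            B = "fold B (trained on A)"))) +
    ggplot2::labs(x = NULL, y = "subject nQi",
                  title = "Cross-dataset validated nQi by group") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot the per-window feature distributions of a cohort
#'
#' @param features A [featurize()] table.
#' @param meta Optional metadata to colour windows by diagnostic group.
#' @return A ggplot: one density panel per feature.
#' @export
plot_feature_distributions <- function(features, meta = NULL) {
  long <- tidyr::pivot_longer(features, dplyr::all_of(FEATURE_COLUMNS),
                              names_to = "feature")
  if (!is.null(meta)) {
    long <- dplyr::inner_join(long, meta[, c("subject_id", "group")],
                              by = "subject_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                            colour = .data$group))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value))
  }
  p +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = "feature value", y = "density",
                  title = "Per-window feature distributions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
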
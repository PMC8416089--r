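#' Volcano plot of a differential table
#'
#' log2 fold change (case over control) against -log10 p, colored by
#' status. Group-exclusive proteins have no p-value and are omitted.
#'
#' @param diff_table Result of [differential_table()].
#' @param alpha Significance level drawn as a guide line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff_table, alpha = attr(diff_table, "alpha") %||% 0.05) {
  dat <- dplyr::filter(diff_table, !is.na(.data$p_value))
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = expression(-log[10] ~ p),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-sample signature scores by group
#'
#' Jittered per-sample mean signature Z-scores, the usual companion of a
#' one-tailed Mann-Whitney comparison of the two arms.
#'
#' @param scores Tibble from [mean_signature_score()].
#' @param annotation Sample annotation tibble.
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(scores, annotation) {
  dat <- dplyr::inner_join(scores, annotation, by = "sample")
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "mean signature Z-score") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.detection_partition <- function(object, ...) {
  dat <- tidyr::pivot_longer(glance(object)[1:4], dplyr::everything(),
                             names_to = "category", values_to = "n")
  dat$category <- sub("^n_", "", dat$category)
  ggplot2::ggplot(dat, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proteins") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gsea_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$position, linetype = "dashed") +
    ggplot2::labs(x = "rank position", y = "running enrichment score",
                  title = sprintf("ES = %.3f, NES = %.3f, p = %.3g",
                                  object$es, object$nes, object$p_value)) +
    ggplot2::theme_minimal()
}
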
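#' Plot sample PCA scores
#'
#' @param object A `qmi_pca` object.
#' @param meta Optional sample metadata; points are colored by `colour`.
#' @param colour Metadata column to color by (default `"condition"`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qmi_pca <- function(object, meta = NULL, colour = "condition", ...) {
  df <- object$scores
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, meta, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(meta) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Bar plot of per-sample module activity by group
#'
#' @param object A `qmi_activity` object.
#' @param ... Unused.
#' @return A ggplot: group means of the mean scaled value with per-sample
#'   points overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.qmi_activity <- function(object, ...) {
  ggplot2::ggplot(object$activity, ggplot2::aes(.data$group, .data$activity)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = "mean scaled value") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' Tiles colored by Pearson r, annotated with r and p, one row per module and
#' one column per coded hypothesis.
#'
#' @param cna A `qmi_cna` object fit with traits.
#' @return A ggplot.
#' @export
plot_module_trait <- function(cna) {
  if (is.null(cna$module_trait)) abort("CNA fit has no module-trait table")
  ggplot2::ggplot(cna$module_trait,
                  ggplot2::aes(.data$hypothesis, .data$module, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.2g)", .data$r, .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Heatmap of median-scaled values
#'
#' @param scaled Output of [scale_by_row_median()].
#' @param interactions Optional subset/ordering of rows (e.g. the
#'   high-confidence set, ordered by first time point of significance).
#' @return A ggplot tile heatmap of log2 scaled values.
#' @export
plot_scaled_heatmap <- function(scaled, interactions = NULL) {
  long <- tibble::as_tibble(scaled) |>
    tidyr::pivot_longer(-"interaction", names_to = "sample_id",
                        values_to = "scaled")
  if (!is.null(interactions)) {
    long <- dplyr::filter(long, .data$interaction %in% interactions) |>
      dplyr::mutate(interaction = factor(.data$interaction, rev(interactions)))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$interaction,
                                     fill = log2(.data$scaled))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 scaled") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
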
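# ggplot2 graphics for the result types.

#' Plot an ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_roc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "Empirical ROC curve") +
    ggplot2::theme_minimal()
}

#' Plot per-marker AUCs from a marker evaluation
#'
#' Oriented AUCs ordered by rank, with the study's tier thresholds drawn.
#'
#' @param object A `marker_eval` table.
#' @param top Number of top markers to show (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marker_eval <- function(object, top = 25, ...) {
  dd <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$auc_oriented)) |>
    dplyr::arrange(dplyr::desc(.data$auc_oriented)) |>
    dplyr::slice_head(n = top)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$auc_oriented,
                                   y = stats::reorder(.data$marker, .data$auc_oriented),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(0.7, 0.75, 0.8, 0.9),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "AUC (oriented)", y = NULL,
                  colour = paste0("q ≤ ", attr(object, "fdr")),
                  title = unique(dd$contrast)) +
    ggplot2::theme_minimal()
}

#' Plot aggregated glycan feature abundances by group
#'
#' @param features An [aggregate_features()] result.
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param classes Optional subset of feature classes to show.
#' @return A ggplot (log10 boxplots per feature class and group).
#' @export
plot_feature_abundance <- function(features, meta, classes = NULL) {
  dd <- dplyr::inner_join(features, meta[, c("sample_id", "group")],
                          by = "sample_id")
  if (!is.null(classes)) dd <- dplyr::filter(dd, .data$feature %in% classes)
  dd$group <- factor(dd$group, levels = c("control", "early", "late"))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$group, y = .data$area,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Summed normalized intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
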
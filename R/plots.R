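#' Plot the top of a SHAP feature ranking
#'
#' @param object A [shap_ranking()] tibble.
#' @param n_top Features to show (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of mean |SHAP| importance.
#' @export
autoplot.shap_ranking <- function(object, n_top = 20, ...) {
  d <- utils::head(object, n_top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$feature,
                                                     .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |SHAP|", y = NULL,
                  title = "Features ranked by SHAP importance") +
    ggplot2::theme_minimal()
}

#' Volcano plot of class-level statistics
#'
#' One point per (class, direction) group, positioned by mean log2 fold
#' change and -log10 Tippett q-value.
#'
#' @param class_results Output of [class_statistics()].
#' @param alpha Significance line (default 0.05).
#' @return A ggplot object.
#' @export
plot_class_volcano <- function(class_results, alpha = 0.05) {
  ggplot2::ggplot(class_results,
                  ggplot2::aes(x = .data$mean_log2fc,
                               y = -log10(.data$q_value),
                               colour = .data$direction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$class), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(down = "#2166AC", up = "#B2182B")) +
    ggplot2::labs(x = "mean log2 fold change", y = "-log10 q (Tippett + BH)") +
    ggplot2::theme_minimal()
}

#' Rescue scatter coloured by diagonal cosine
#'
#' WT vs mutant luciferase-normalized log2 fold changes with the 1:1
#' diagonal; divergent (low-cosine) genes fall off the line.
#'
#' @param rescue Output of [rescue_divergence()].
#' @return A ggplot object.
#' @export
plot_rescue_cosine <- function(rescue) {
  ggplot2::ggplot(rescue, ggplot2::aes(x = .data$norm_wt, y = .data$norm_mut,
                                       colour = .data$cosine)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "WT rescue log2FC (luciferase-normalized)",
                  y = "mutant rescue log2FC (luciferase-normalized)",
                  colour = "cosine") +
    ggplot2::theme_minimal()
}

#' Linkage-type proportions by gene set
#'
#' @param summary Output of [linkage_summary()].
#' @return A ggplot stacked-proportion bar chart.
#' @export
plot_linkage_types <- function(summary) {
  d <- summary$per_gene |>
    dplyr::filter(.data$n_linked_enhancers >= 1 | .data$linkage_type == "promoter-only") |>
    dplyr::count(.data$signature, .data$linkage_type) |>
    dplyr::group_by(.data$signature) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = ifelse(.data$signature, "signature",
                                             "non-signature"),
                                  y = .data$prop, fill = .data$linkage_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of genes", fill = "linkage") +
    ggplot2::theme_minimal()
}
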
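#' Plot a weighted matrix
#'
#' Heatmap of the interaction matrix; when a partition is supplied, rows
#' and columns are ordered by module (then by marginal total within module)
#' so the modular block structure is visible.
#'
#' @param object A [weighted_matrix()].
#' @param partition Optional [module_partition()] used to order nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.weighted_matrix <- function(object, partition = NULL, ...) {
  a <- unclass(object)
  if (!is.null(partition)) {
    v <- partition_vectors(object, partition)
    ro <- order(v$zr, -rowSums(a))
    co <- order(v$zc, -colSums(a))
    a <- a[ro, co, drop = FALSE]
  }
  df <- tibble::as_tibble(as.data.frame(a), rownames = "resource") |>
    tidyr::pivot_longer(-"resource", names_to = "consumer", values_to = "weight")
  df$resource <- factor(df$resource, levels = rev(rownames(a)))
  df$consumer <- factor(df$consumer, levels = colnames(a))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consumer, y = .data$resource,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::labs(x = "consumers", y = "resources", fill = "events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot the z-score surface of a full analysis
#'
#' Dot plot of every standardized metric in the report (network-level
#' modularity and nestedness, per-module WNODA, FDis and CWM) with the
#' |z| = 2 significance band.
#'
#' @param object A `network_analysis` from [run_full_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.network_analysis <- function(object, ...) {
  df <- tidy(object)
  df$label <- ifelse(is.na(df$module), df$metric,
                     paste0(df$metric, " m", df$module,
                            ifelse(is.na(df$trait), "", paste0(" ", df$trait))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$label,
                                   colour = .data$interpretation)) +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$network), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "z-score", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Abundance-degree scatter plot
#'
#' Degree against log10 abundance with the fitted least-squares line, the
#' diagnostic view of the abundance-based assembly signal.
#'
#' @param data Data frame with `abundance` and `degree` columns.
#' @return A ggplot object.
#' @export
plot_abundance_degree <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = log10(.data$abundance), y = .data$degree)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10(abundance)", y = "degree") +
    ggplot2::theme_minimal()
}
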
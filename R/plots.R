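# ggplot2 convenience layers for the main result types.

#' Plot similarity summaries across the density grid
#'
#' Mean +/- SD of a similarity statistic per contrast across densities, the
#' standard way intermodel / retest / group results are displayed.
#'
#' @param summary A summary tibble from [run_intermodel()],
#'   [run_test_retest()] or [run_subject_vs_group()].
#' @param statistic Which statistic to plot (default `"r_all"`).
#' @return A ggplot object.
#' @export
plot_similarity_summary <- function(summary, statistic = "r_all") {
  df <- dplyr::filter(summary, .data$statistic == !!statistic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$mean,
                                   colour = .data$contrast,
                                   fill = .data$contrast)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "edge density", y = statistic) +
    ggplot2::theme_minimal()
}

#' Heatmap of an MSN or group network
#'
#' @param w An `msn_matrix`, `thresholded_msn` or square matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_msn <- function(w, title = NULL) {
  w <- .net_weights(w)
  df <- tibble::as_tibble(as.table(w), .name_repair = ~c("row", "col", "weight"))
  df$row <- factor(df$row, levels = rev(rownames(w)))
  df$col <- factor(df$col, levels = colnames(w))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a PLS selection result
#'
#' Bar chart of how often each component count maximized the cross-validated
#' Q^2, with the chosen (modal) count highlighted — the selection evidence
#' behind "no models were built" when the zero-component bar dominates.
#'
#' @param object A `pls_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_selection <- function(object, ...) {
  df <- object$selection_counts
  df$chosen <- df$ncomp == object$chosen_c
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$ncomp), y = .data$count,
                                   fill = .data$chosen)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "components retained",
                  y = "CV instances with greatest Q²") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
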
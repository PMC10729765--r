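#' Heatmap of a connectivity matrix
#'
#' @param object A `wpli_connectivity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wpli_connectivity
#' @export
autoplot.wpli_connectivity <- function(object, ...) {
  df <- tidy(object)
  both <- dplyr::bind_rows(
    df,
    dplyr::rename(df, ch1 = "ch2", ch2 = "ch1"))
  lv <- object$channel_names
  both$ch1 <- factor(both$ch1, levels = lv)
  both$ch2 <- factor(both$ch2, levels = rev(lv))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$ch1, y = .data$ch2,
                                     fill = .data$wpli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "wPLI") +
    ggplot2::labs(
      title = sprintf("wPLI connectivity (%s band, %d epochs)",
                      object$band_name, object$n_epochs),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano-style view of an edgewise comparison
#'
#' Plots each edge's group difference against its adjusted p value,
#' highlighting FDR-significant edges.
#'
#' @param object An `edge_stats` tibble from [edgewise_ttest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edge_stats
#' @export
autoplot.edge_stats <- function(object, ...) {
  df <- dplyr::mutate(object, diff = .data$mean_a - .data$mean_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick"),
                                name = "FDR significant") +
    ggplot2::labs(x = "mean wPLI difference (group A - group B)",
                  y = expression(-log[10] ~ adjusted ~ italic(p))) +
    ggplot2::theme_minimal()
}

#' Per-band significant-edge counts of a pipeline run
#'
#' @param object A `network_comparison` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot network_comparison
#' @export
autoplot.network_comparison <- function(object, ...) {
  df <- object$edge_stats |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$band, .data$direction)
  df$band <- factor(df$band, levels = unique(object$edge_stats$band))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(increase = "firebrick",
                                          decrease = "steelblue")) +
    ggplot2::labs(x = NULL, y = "FDR-significant edges",
                  fill = "group A vs B") +
    ggplot2::theme_minimal()
}

#' Sensitivity-table trend plot
#'
#' @param object A `sensitivity_table` from [sensitivity_harness()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$epoch_length, y = .data$mean_wpli,
    color = factor(.data$rate), group = factor(.data$rate))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_wpli - .data$sd_wpli,
      ymax = .data$mean_wpli + .data$sd_wpli)) +
    ggplot2::labs(x = "epoch length (s)", y = "mean null wPLI",
                  color = "rate (Hz)") +
    ggplot2::theme_minimal()
}
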
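# Heatmap-style figures for mode comparisons.

#' MAC heatmap of a mode comparison
#'
#' @param cmp a [compare_modes()] result (or a plain MAC matrix).
#' @return a ggplot object (modes of A on the y axis, modes of B on x,
#'   fill = MAC).
#' @export
plot_mac_heatmap <- function(cmp) {
  mm <- if (inherits(cmp, "mode_comparison")) cmp$mac else as.matrix(cmp)
  df <- expand.grid(mode_A = seq_len(nrow(mm)), mode_B = seq_len(ncol(mm)))
  df$mac <- as.vector(mm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode_B, y = .data$mode_A,
                                   fill = .data$mac)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "MAC") +
    ggplot2::scale_y_reverse(breaks = pretty) +
    ggplot2::scale_x_continuous(breaks = pretty) +
    ggplot2::labs(x = "mode (validation model)",
                  y = "mode (reference model)") +
    ggplot2::theme_minimal()
}

#' NRFD bar chart of the paired modes
#'
#' @param cmp a [compare_modes()] result whose pairs carry frequencies.
#' @return a ggplot object (NRFD per reference mode index).
#' @export
plot_nrfd <- function(cmp) {
  stopifnot(inherits(cmp, "mode_comparison"))
  if (is.null(cmp$pairs$nrfd)) stop("comparison has no NRFD values")
  ggplot2::ggplot(cmp$pairs, ggplot2::aes(x = .data$i, y = .data$nrfd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = pretty) +
    ggplot2::labs(x = "mode (reference model)", y = "NRFD") +
    ggplot2::theme_minimal()
}
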
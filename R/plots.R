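#' Plot a reclassification table
#'
#' Tile map of the weighted 4x4 FRS-by-RRS cross-tabulation, cell labels
#' in millions of persons. Off-diagonal mass above the diagonal is
#' upward reclassification.
#'
#' @param object A `cvr_reclass` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cvr_reclass <- function(object, ...) {
  df <- as.data.frame.table(object$xtab, responseName = "weight")
  names(df)[1:2] <- c("frs", "rrs")
  df$frs <- factor(df$frs, category_levels)
  df$rrs <- factor(df$rrs, category_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rrs, y = .data$frs,
                                   fill = .data$weight / 1e6)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$weight / 1e6)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "millions") +
    ggplot2::scale_y_discrete(limits = rev(category_levels)) +
    ggplot2::labs(x = "RRS category", y = "FRS category",
                  title = "Weighted risk-category reclassification") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of paired per-subject risks
#'
#' FRS against RRS on the ten-year risk scale with the category cuts
#' drawn, coloured by reclassification direction; the visual companion
#' to [reclassification_table()].
#'
#' @param assessed Output of [assess_goals()].
#' @return A ggplot.
#' @export
plot_risk_comparison <- function(assessed) {
  cuts <- c(0.06, 0.10, 0.20)
  ggplot2::ggplot(assessed,
                  ggplot2::aes(x = .data$frs_risk, y = .data$rrs_risk,
                               color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = cuts, color = "grey60") +
    ggplot2::geom_hline(yintercept = cuts, color = "grey60") +
    ggplot2::scale_x_sqrt(labels = function(x) sprintf("%g%%", 100 * x)) +
    ggplot2::scale_y_sqrt(labels = function(x) sprintf("%g%%", 100 * x)) +
    ggplot2::labs(x = "FRS 10-year risk", y = "RRS 10-year risk",
                  color = "reclassified") +
    ggplot2::theme_minimal()
}
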
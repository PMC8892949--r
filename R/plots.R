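#' Plot a concordance landscape in treespace
#'
#' Scatter of the principal-coordinate embedding of the Robinson-Foulds
#' matrix: one point per clade arrangement, point size encoding mean gene
#' concordance and color mean site concordance; the arrangement with the
#' top mean gCF is outlined.
#'
#' @param object A `tree_landscape`.
#' @param label Logical; draw the two-letter identifiers (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tree_landscape <- function(object, label = FALSE, ...) {
  df <- tidy(object)
  best <- df[which.max(df$mean_gcf), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_gcf,
                                     color = .data$mean_scf), alpha = 0.85) +
    ggplot2::geom_point(data = best, shape = 21, stroke = 1.2,
                        color = "darkred", fill = NA,
                        ggplot2::aes(size = .data$mean_gcf)) +
    ggplot2::scale_color_viridis_c(name = "mean sCF") +
    ggplot2::scale_size_continuous(name = "mean gCF") +
    ggplot2::labs(x = "PCo axis 1 (RF)", y = "PCo axis 2 (RF)") +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$topology_id),
                                size = 2.5, vjust = -1)
  }
  p
}

#' Plot a likelihood-mapping census
#'
#' Bar chart of total quartet counts over the seven simplex regions.
#'
#' @param object An `lmap_census`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lmap_census <- function(object, ...) {
  regions <- c("corner1", "corner2", "corner3", "side12", "side13",
               "side23", "center")
  df <- tibble(region = factor(regions, levels = regions),
               count = as.numeric(object$totals[regions]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "quartets") +
    ggplot2::theme_minimal()
}

#' Plot per-map transition counts
#'
#' Histogram of total transitions per stochastic map, split by terminal
#' versus internal branches.
#'
#' @param object A `transition_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_map, c("terminal", "internal"),
                            names_to = "branch_class", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count,
                                   fill = .data$branch_class)) +
    ggplot2::geom_histogram(position = "dodge", bins = 20) +
    ggplot2::labs(x = "transitions per map", y = "maps", fill = NULL) +
    ggplot2::theme_minimal()
}
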
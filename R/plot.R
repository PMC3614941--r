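#' Overview plot of all persistence diagrams
#'
#' One point per cluster label at (maximum scale persistence, maximum
#' density persistence), sized by the largest conformation count the
#' cluster attains. Reliable metastable states sit towards the upper right;
#' rare but kinetically distinct states show long scale persistence with a
#' high birth level.
#'
#' @param object an `mpc_summary` (or `mpc_candidates`) tibble.
#' @param label_top annotate the `label_top` largest-area points.
#' @param ... unused.
#' @return a ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot mpc_summary
#' @export
autoplot.mpc_summary <- function(object, label_top = 6L, ...) {
  df <- tibble::as_tibble(object)
  df$area <- df$scale_persistence * df$density_persistence
  top <- utils::head(df[order(-df$area), ], label_top)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$scale_persistence, y = .data$density_persistence,
    size = .data$max_size)) +
    ggplot2::geom_point(alpha = 0.6,
                        position = ggplot2::position_jitter(
                          width = 0.15, height = 0.15, seed = 1)) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$label),
                       size = 3, vjust = -1) +
    ggplot2::labs(x = "max scale persistence (grid indices)",
                  y = "max density persistence (grid indices)",
                  size = "max conformations") +
    ggplot2::theme_minimal()
  if ("selected" %in% names(df))
    p <- p + ggplot2::aes(colour = ifelse(
      object$selected, "selected",
      ifelse(object$rare_state, "rare-state", "other"))) +
      ggplot2::labs(colour = NULL)
  p
}

#' Persistence-region diagrams
#'
#' Tile plot of the persistence regions of chosen labels over the
#' (scale index, density level) grid, filled by cluster size, one facet
#' per cluster label.
#'
#' @param object an `mpc_regions` collection.
#' @param labels original microstate labels to show; default: the 6 regions
#'   of largest cell count.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mpc_regions
#' @export
autoplot.mpc_regions <- function(object, labels = NULL, ...) {
  cells <- tidy.mpc_regions(object)
  if (is.null(labels)) {
    sizes <- sort(table(cells$label), decreasing = TRUE)
    labels <- as.integer(names(sizes)[seq_len(min(6L, length(sizes)))])
  }
  cells <- cells[cells$label %in% labels, ]
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$l, y = .data$j, fill = .data$size)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~label, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "scale index", y = "density level (more states ↑)",
                  fill = "conformations") +
    ggplot2::theme_minimal()
}

#' Plot a cluster hierarchy
#'
#' Thin wrapper over [ape::plot.phylo()]; node heights are density-level
#' indices at the hierarchy's reference scale.
#'
#' @param x an `mpc_hierarchy`.
#' @param ... forwarded to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.mpc_hierarchy <- function(x, ...) {
  ape::plot.phylo(x$phylo, ...)
  invisible(x)
}

#' @export
ggplot2::autoplot
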
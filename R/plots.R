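#' Plot the InDel molecular index distribution
#'
#' Histogram of per-sample japonica-allele frequency with the seven
#' classification bands shaded.
#'
#' @param object an `indel_index` tibble from [classify_panel()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot indel_index
#' @export
#' @importFrom ggplot2 autoplot
autoplot.indel_index <- function(object, ...) {
  breaks <- c(0, fj_breaks(), 1)
  bands <- tibble::tibble(xmin = breaks[-length(breaks)], xmax = breaks[-1],
                          class = factor(subspecies_levels(),
                                         levels = subspecies_levels()))
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf, fill = .data$class),
                       alpha = 0.25) +
    ggplot2::geom_histogram(ggplot2::aes(x = .data$f_j), bins = 40,
                            colour = "grey20", fill = "grey40", na.rm = TRUE) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", name = "class") +
    ggplot2::labs(x = "japonica-specific allele frequency (F_j)",
                  y = "samples") +
    ggplot2::theme_minimal()
}

#' Plot an ordination
#'
#' Scatter of the first two axes, optionally coloured by a grouping.
#'
#' @param object an `indel_ordination`
#' @param colour optional vector (aligned with the scores) used for colour
#' @param ... unused
#' @return a ggplot
#' @method autoplot indel_ordination
#' @export
autoplot.indel_ordination <- function(object, colour = NULL, ...) {
  sc <- object$scores
  if (!is.null(colour)) sc$group <- colour
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("axis 1 (%.2f%%)", object$pct_variance[1]),
      y = sprintf("axis 2 (%.2f%%)", object$pct_variance[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point(alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
}

#' Plot an AMOVA variance partition
#'
#' @param object an `indel_amova`
#' @param ... unused
#' @return a ggplot of the estimated variance components
#' @method autoplot indel_amova
#' @export
autoplot.indel_amova <- function(object, ...) {
  s <- object$sources[object$sources$source != "total", ]
  ggplot2::ggplot(s, ggplot2::aes(x = "", y = .data$pct, fill = .data$source)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::labs(x = NULL, y = "% of molecular variance",
                  subtitle = sprintf("Phi-PT = %.3f", object$phi_pt)) +
    ggplot2::theme_minimal()
}

#' Plot a UPGMA dendrogram
#'
#' Segment-based ggplot rendering of the tree, with heights on the
#' distance/2 scale; for Jaccard-based trees the y axis can be read as
#' (1 - similarity) / 2.
#'
#' @param tree an `indel_upgma`
#' @param labels draw leaf labels (sensible only for small trees)
#' @return a ggplot
#' @export
plot_dendrogram <- function(tree, labels = length(tree$labels) <= 40) {
  hc <- tree$hclust
  n <- length(hc$labels)
  # x position of each leaf in plotting order
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(length(hc$height))
  node_y <- hc$height / 2
  segs <- list()
  pos <- function(k) if (k < 0) c(leaf_x[-k], 0) else c(node_x[k], node_y[k])
  for (i in seq_along(hc$height)) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    segs[[i]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_y[i]), yend = c(node_y[i], node_y[i], node_y[i]))
  }
  segs <- dplyr::bind_rows(segs)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "merge height (distance / 2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
  if (labels) {
    lab <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                                angle = 90, hjust = 1.1, size = 2.5)
  }
  p
}
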
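#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_segment autoplot
#'   facet_wrap labs theme_minimal scale_color_viridis_c geom_text
NULL

group_col <- function(df) {
  cand <- intersect(c("group", "top_group", "tissue", "sample_id"), names(df))
  if (length(cand) == 0) NULL else cand[[1]]
}

#' @export
autoplot.epic_pca <- function(object, ...) {
  sc <- object$scores
  col <- group_col(sc)
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) + theme_minimal()
  p <- if (is.null(col)) p + geom_point()
       else p + geom_point(aes(color = .data[[col]]))
  ve <- object$var_explained
  p + labs(
    x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * ve[min(2, length(ve))]),
    title = "PCA of methylation beta values"
  )
}

dendrogram_coords <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- match(seq_len(n), hc$order)
  node_x <- numeric(n - 1); node_y <- hc$height
  xpos <- function(v) if (v < 0) leaf_x[-v] else node_x[v]
  ypos <- function(v) if (v < 0) 0 else node_y[v]
  segs <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    xl <- xpos(hc$merge[i, 1]); xr <- xpos(hc$merge[i, 2])
    yl <- ypos(hc$merge[i, 1]); yr <- ypos(hc$merge[i, 2])
    node_x[i] <- (xl + xr) / 2
    segs[[i]] <- tibble(
      x = c(xl, xr, xl), xend = c(xl, xr, xr),
      y = c(yl, yr, node_y[i]), yend = rep(node_y[i], 3),
      node = i
    )
  }
  list(segments = bind_rows(segs),
       nodes = tibble(node = seq_len(n - 1), x = node_x, y = node_y),
       leaves = tibble(label = hc$labels, x = leaf_x, y = 0))
}

#' @export
autoplot.epic_dendrogram <- function(object, show_support = TRUE, ...) {
  co <- dendrogram_coords(object$hc)
  p <- ggplot() +
    geom_segment(data = co$segments,
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_text(data = co$leaves,
              aes(x = .data$x, y = .data$y, label = .data$label),
              angle = 90, hjust = 1.05, size = 2.5) +
    theme_minimal() +
    labs(x = NULL, y = "Ward.D height",
         title = "Hierarchical clustering of samples")
  if (show_support && !is.null(object$support)) {
    nd <- co$nodes
    nd$support <- object$support
    p <- p + geom_text(data = nd,
                       aes(x = .data$x, y = .data$y,
                           label = sprintf("%.2f", .data$support)),
                       vjust = -0.4, size = 2.5, color = "grey30")
  }
  p
}

#' Plot windowed probe density along chromosomes
#'
#' @param density Tibble from [windowed_density()].
#' @return A ggplot object.
#' @export
plot_density_profile <- function(density) {
  ggplot(density, aes(x = .data$start / 1e6, y = .data$n)) +
    geom_col(width = diff(range(density$start / 1e6)) /
               max(length(unique(density$start)), 1)) +
    facet_wrap(~chrom, scales = "free_x") +
    theme_minimal() +
    labs(x = "Position (Mb)", y = "Probes per window",
         title = "Probe density in fixed-width windows")
}

#' Plot a beta-difference histogram
#'
#' @param hist Tibble from [beta_difference_density()].
#' @return A ggplot object.
#' @export
plot_beta_difference <- function(hist) {
  ggplot(hist, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = hist$bin_right[1] - hist$bin_left[1]) +
    theme_minimal() +
    labs(x = "Beta difference (x - y)", y = "Probes",
         title = "Distribution of paired beta differences")
}

#' Plot annotation category summaries
#'
#' @param categories Tibble from [summarize_categories()].
#' @return A ggplot object.
#' @export
plot_category_summary <- function(categories) {
  ggplot(categories, aes(x = .data$category, y = .data$pct)) +
    geom_col() +
    facet_wrap(~dimension, scales = "free_x") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    labs(x = NULL, y = "% of probes", title = "Probe annotation categories")
}

#' Plot a 2D sample embedding (t-SNE or any scores tibble)
#'
#' @param scores Tibble with two coordinate columns and optional grouping.
#' @param x,y Coordinate column names (default `tsne1`, `tsne2`).
#' @return A ggplot object.
#' @export
plot_embedding <- function(scores, x = "tsne1", y = "tsne2") {
  col <- group_col(scores)
  p <- ggplot(scores, aes(x = .data[[x]], y = .data[[y]])) + theme_minimal()
  if (is.null(col)) p + geom_point()
  else p + geom_point(aes(color = .data[[col]])) +
    labs(title = "Sample embedding")
}

#' Bubble plot of over-representation results
#'
#' Fold enrichment on the x axis, one row per set, bubble size/colour by
#' FDR.
#'
#' @param results Tibble from [fisher_ora()] (typically after
#'   [significant_sets()]).
#' @param top Show at most this many sets (by q).
#' @return A ggplot object.
#' @export
plot_ora <- function(results, top = 20) {
  df <- head(arrange(results, .data$q), top)
  df$label <- dplyr::coalesce(df$name, df$set_id)
  ggplot(df, aes(x = .data$fold,
                 y = stats::reorder(.data$label, .data$fold))) +
    geom_point(aes(size = .data$k, color = .data$q)) +
    scale_color_viridis_c(direction = -1) +
    theme_minimal() +
    labs(x = "Fold enrichment (observed/expected)", y = NULL,
         size = "Study hits", color = "FDR",
         title = "Gene-set over-representation")
}
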
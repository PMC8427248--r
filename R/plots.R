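# ggplot2 autoplot methods for the result objects

#' Plot a trait correlation matrix
#'
#' Lower-triangle heatmap of Pearson correlations; pairs significant at the
#' object's `alpha` are starred.
#'
#' @param object A [trait_correlation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_correlation <- function(object, ...) {
  td <- tidy(object)
  td$label <- sprintf("%.2f%s", td$r, ifelse(td$significant, "*", ""))
  traits <- colnames(object$r)
  td$trait1 <- factor(td$trait1, levels = traits)
  td$trait2 <- factor(td$trait2, levels = rev(traits))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$trait1, y = .data$trait2,
                                   fill = .data$r)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  caption = sprintf("* p < %.2g (two-tailed, df = %d)",
                                    object$alpha, object$n - 2)) +
    ggplot2::theme_minimal()
}

#' Biplot of a genotype-by-trait PCA
#'
#' Genotype scores on two components with trait loading vectors overlaid
#' (scaled to the score range).
#'
#' @param object A [trait_pca()] result.
#' @param components Two components to display (default first two).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_pca <- function(object, components = c(1, 2), ...) {
  stopifnot(length(components) == 2)
  sc <- tidy(object, matrix = "scores")
  ld <- tidy(object, matrix = "loadings")
  cn <- colnames(object$loadings)[components]
  mult <- 0.8 * min(
    max(abs(sc[[cn[1]]])) / max(abs(ld[[cn[1]]])),
    max(abs(sc[[cn[2]]])) / max(abs(ld[[cn[2]]]))
  )
  lab <- sprintf("%s (%.1f%%)", cn, object$variability_pct[components])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[cn[1]]], y = .data[[cn[2]]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype),
                       vjust = -0.6, size = 2.8) +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0,
                                       xend = .data[[cn[1]]] * mult,
                                       yend = .data[[cn[2]]] * mult),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          color = "#b2182b") +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(x = .data[[cn[1]]] * mult * 1.08,
                                    y = .data[[cn[2]]] * mult * 1.08,
                                    label = .data$trait),
                       color = "#b2182b", size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

# rectangular dendrogram segments from an hclust object
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  pos <- function(id) {
    if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_y[id])
  }
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble(
      x = c(a[1], b[1], a[1]), y = c(a[2], b[2], hc$height[i]),
      xend = c(a[1], b[1], b[1]), yend = c(hc$height[i], hc$height[i], hc$height[i])
    )
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram of a genotype clustering
#'
#' @param object A [hierarchical_cluster()] result.
#' @param ... Unused.
#' @return A ggplot with merge heights on the y axis (Euclidean distance
#'   units) and leaves labelled by genotype, coloured by cluster.
#' @export
autoplot.genotype_clusters <- function(object, ...) {
  hc <- object$hclust
  segs <- hclust_segments(hc)
  leaves <- tibble(
    genotype = hc$labels[hc$order],
    x = seq_along(hc$order), y = 0
  )
  leaves <- dplyr::left_join(leaves, object$assignment, by = "genotype")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$genotype,
                                    color = factor(.data$cluster)),
                       angle = 90, hjust = 1.05, size = 2.8) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "Euclidean distance", color = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot genotype means with letter groups
#'
#' Genotype means with +/- one standard deviation bars and the compact letter
#' display, one facet per trait.
#'
#' @param object A [mean_separation()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mean_separation <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$group,
                                    y = .data$mean + .data$sd),
                       vjust = -0.5, size = 2.8) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "genotype mean ± sd") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Plot a genetic parameter summary
#'
#' Side-by-side GCV/PCV bars plus heritability and GAM panels.
#'
#' @param object A [genetic_summary()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genetic_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[, c("trait", "gcv", "pcv", "h2", "gam")],
                           cols = c("gcv", "pcv", "h2", "gam"),
                           names_to = "parameter", values_to = "value")
  d$parameter <- factor(d$parameter, levels = c("gcv", "pcv", "h2", "gam"),
                        labels = c("GCV (%)", "PCV (%)",
                                   "heritability (%)", "GAM (%)"))
  d$trait <- factor(d$trait, levels = unique(object$trait))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
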
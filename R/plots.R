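#' Heatmap of a correlation matrix in seriated order
#'
#' @param object A `correlation_matrix`.
#' @param order_genes Seriate the genes first (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, order_genes = TRUE, ...) {
  ord <- if (order_genes) seriate_genes(object) else object$genes
  df <- tidy.correlation_matrix(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, gene_a = "gene_b", gene_b = "gene_a"),
    tibble(gene_a = object$genes, gene_b = object$genes, r = 1, p = 0))
  df2$gene_a <- factor(df2$gene_a, levels = ord)
  df2$gene_b <- factor(df2$gene_b, levels = ord)
  ggplot2::ggplot(df2, ggplot2::aes(.data$gene_a, .data$gene_b,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Null histogram of a correlation-pattern permutation test
#'
#' @param object A `perm_pattern_test`.
#' @param ... Unused.
#' @return A ggplot object: histogram of null pair counts with the
#'   observed count marked.
#' @method autoplot perm_pattern_test
#' @export
autoplot.perm_pattern_test <- function(object, ...) {
  df <- tidy.perm_pattern_test(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_count,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "significant pairs in random gene group",
      y = "random groups",
      title = sprintf("observed = %d, empirical p = %.4g",
                      object$observed_count, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Profile-correlation curve of an expanded gene list
#'
#' @param object An `expanded_gene_list`.
#' @param ... Unused.
#' @return A ggplot object: correlation to the cluster profile by rank,
#'   seed genes highlighted.
#' @method autoplot expanded_gene_list
#' @export
autoplot.expanded_gene_list <- function(object, ...) {
  df <- object$members |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$r_to_profile,
                                   colour = .data$is_seed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "rank", y = "correlation with cluster profile",
                  colour = "seed gene") +
    ggplot2::theme_minimal()
}

#' Plot a pathway deviation network
#'
#' Deterministic Fruchterman-Reingold layout; node colour encodes the
#' deviation score (case mean minus control mean, in control SD units).
#'
#' @param object A `deviation_network`.
#' @param layout_seed Seed for the layout (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deviation_network
#' @export
autoplot.deviation_network <- function(object, layout_seed = 1, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  g <- object$graph
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(gene = igraph::V(g)$name,
                  deviation = igraph::V(g)$deviation,
                  x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    x = nodes$x[match(el[, 1], nodes$gene)],
    y = nodes$y[match(el[, 1], nodes$gene)],
    xend = nodes$x[match(el[, 2], nodes$gene)],
    yend = nodes$y[match(el[, 2], nodes$gene)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey80") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$deviation), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$gene),
                       vjust = -1, size = 2.5) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red") +
    ggplot2::labs(colour = "(Mp - Mc)/Sc",
                  title = object$pathway_name %||% NULL) +
    ggplot2::theme_void()
}

#' @export
plot.correlation_matrix <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.perm_pattern_test <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.deviation_network <- function(x, ...) print(autoplot(x, ...))
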
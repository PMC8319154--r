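#' Per-gene deviation from the control group
#'
#' For each gene: `Mc` and `Sc` are the mean and standard deviation
#' (denominator n - 1) over control samples only; `Mp` is the mean over
#' case samples; the deviation score is `d = (Mp - Mc) / Sc`. Genes with
#' `Sc = 0` are excluded with a warning.
#'
#' @param es An [expression_set()].
#' @param genes Character vector of genes to score (must be present in the
#'   matrix).
#' @param region Optional region label.
#' @return A tibble with columns `gene`, `m_control`, `s_control`,
#'   `m_case`, `deviation`.
#' @export
deviation_scores <- function(es, genes, region = NULL) {
  stopifnot(inherits(es, "expression_set"))
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(es$values))
  if (length(missing)) {
    abort(paste0("Gene(s) not in the matrix: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  case_ids <- group_samples(es, "case", region, min_n = 3)
  ctrl_ids <- group_samples(es, "control", region, min_n = 3)
  xc <- es$values[genes, case_ids, drop = FALSE]
  xk <- es$values[genes, ctrl_ids, drop = FALSE]
  mc <- unname(rowMeans(xk))
  sc <- unname(apply(xk, 1, sd))
  mp <- unname(rowMeans(xc))
  zero <- sc == 0
  if (any(zero)) {
    warn(paste0("Excluding gene(s) with zero control SD: ",
                paste(genes[zero], collapse = ", ")))
  }
  tibble(gene = genes, m_control = mc, s_control = sc, m_case = mp,
         deviation = (mp - mc) / sc)[!zero, ]
}

#' Build a pathway deviation network
#'
#' Restricts a co-expression edge table to the scored genes, keeps edges
#' with score strictly above `min_score`, drops genes left without any
#' co-expression relation, and attaches the deviation score to each node.
#'
#' @param scores Tibble from [deviation_scores()].
#' @param edges Edge tibble (`gene_a`, `gene_b`, `score`), e.g. from
#'   [read_edges()] or [simulate_edges()].
#' @param min_score Edges must have score strictly greater than this
#'   (default 0.1).
#' @param pathway_name Optional label.
#' @return An object of class `deviation_network`: list with `graph`
#'   (igraph, node attribute `deviation`, edge attribute `score`),
#'   `nodes` (tibble), `edges` (tibble), `pathway_name`. An empty network
#'   (no surviving edge) is returned with a warning, not an error.
#' @export
build_network <- function(scores, edges, min_score = 0.1,
                          pathway_name = NULL) {
  if (nrow(scores) == 0) abort("`scores` is empty.")
  edges <- normalize_edges(edges)
  keep <- edges$gene_a %in% scores$gene & edges$gene_b %in% scores$gene &
    edges$score > min_score
  kept <- edges[keep, ]
  if (nrow(kept) == 0) {
    warn("No edges survive the score threshold; network is empty.")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g,
                          nodes = tibble(gene = character(),
                                         deviation = numeric()),
                          edges = kept, pathway_name = pathway_name),
                     class = "deviation_network"))
  }
  nodes <- scores |>
    dplyr::filter(.data$gene %in% c(kept$gene_a, kept$gene_b)) |>
    dplyr::select("gene", "deviation") |>
    dplyr::arrange(.data$gene)
  g <- igraph::graph_from_data_frame(
    kept, directed = FALSE,
    vertices = data.frame(name = nodes$gene, deviation = nodes$deviation))
  structure(list(graph = g, nodes = nodes, edges = kept,
                 pathway_name = pathway_name),
            class = "deviation_network")
}

#' @export
print.deviation_network <- function(x, ...) {
  cat(sprintf("<deviation_network>%s %d genes, %d edges\n",
              if (is.null(x$pathway_name)) "" else
                paste0(" '", x$pathway_name, "'"),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_network Node table with deviation scores.
#' @param x A `deviation_network`.
#' @param ... Unused.
#' @method tidy deviation_network
#' @export
tidy.deviation_network <- function(x, ...) x$nodes

#' Export a deviation network
#'
#' Writes GraphML (node attribute `deviation`, edge attribute `score`)
#' and/or an edge-list TSV.
#'
#' @param x A `deviation_network`.
#' @param graphml_path,tsv_path Output paths (`NULL` to skip either).
#' @return `x`, invisibly.
#' @export
write_network <- function(x, graphml_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "deviation_network"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(x$graph, graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(x$edges, tsv_path, progress = FALSE)
  }
  invisible(x)
}

#' Exact binomial test for a directional tendency of deviation scores
#'
#' Counts genes with positive and negative deviation (zeros are excluded)
#' and computes the exact one-sided binomial tail in the majority
#' direction: `P(X >= max(n_pos, n_neg))` for
#' `X ~ Binomial(n_pos + n_neg, 1/2)`. A coordinated up- (or down-)
#' regulation of a pathway shows up as a small p even when no single gene
#' is significant. The two-sided value (twice the tail, capped at 1;
#' exact for a symmetric null) is reported alongside.
#'
#' @param scores Tibble from [deviation_scores()] (or any tibble with a
#'   `deviation` column).
#' @param min_nonzero Minimum number of genes with nonzero deviation
#'   (default 5).
#' @return An object of class `tendency_test`: list with `n_pos`, `n_neg`,
#'   `direction` (`"up"`/`"down"`, ties count as up), `p_one_sided`,
#'   `p_two_sided`.
#' @export
tendency_test <- function(scores, min_nonzero = 5) {
  if (!"deviation" %in% names(scores)) {
    abort("`scores` must contain a `deviation` column.")
  }
  d <- scores$deviation
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  n <- n_pos + n_neg
  if (n == 0) abort("All deviation scores are zero.")
  if (n < min_nonzero) {
    abort(sprintf("Need at least %d genes with nonzero deviation; have %d.",
                  min_nonzero, n))
  }
  m <- max(n_pos, n_neg)
  p1 <- pbinom(m - 1, n, 0.5, lower.tail = FALSE)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 direction = if (n_pos >= n_neg) "up" else "down",
                 p_one_sided = p1, p_two_sided = min(1, 2 * p1)),
            class = "tendency_test")
}

#' @export
print.tendency_test <- function(x, ...) {
  cat(sprintf(
    "<tendency_test> %d up / %d down -> %s-regulation, p = %.4g (one-sided)\n",
    x$n_pos, x$n_neg, x$direction, x$p_one_sided))
  invisible(x)
}

#' @describeIn tendency_test One-row summary tibble.
#' @param x A `tendency_test`.
#' @param ... Unused.
#' @method glance tendency_test
#' @export
glance.tendency_test <- function(x, ...) {
  tibble(n_pos = x$n_pos, n_neg = x$n_neg, direction = x$direction,
         p_one_sided = x$p_one_sided, p_two_sided = x$p_two_sided)
}

#' @describeIn tendency_test Same as `glance()`.
#' @method tidy tendency_test
#' @export
tidy.tendency_test <- function(x, ...) glance.tendency_test(x)
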
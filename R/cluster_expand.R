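#' Seriate a correlation matrix
#'
#' Orders genes so that co-expressed genes sit next to each other: the
#' leaf order of average-linkage hierarchical clustering on the distance
#' `1 - r`. Ties are broken deterministically by sorting the input genes
#' by name before clustering.
#'
#' @param cm A `correlation_matrix` (see [pairwise_correlation()]).
#' @return Character vector: the genes in seriated order.
#' @export
seriate_genes <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  ord0 <- order(cm$genes)
  r <- cm$r[ord0, ord0]
  genes <- cm$genes[ord0]
  if (length(genes) < 3) return(genes)
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  genes[hc$order]
}

#' Identify the highly correlated sub-cluster of a gene list
#'
#' Scans contiguous windows of the seriated gene order. Among windows of
#' size at least `min_size` with mean pairwise correlation at least
#' `min_mean_r`, the detector picks the window maximizing the total
#' excess correlation `n_pairs * (mean_r - min_mean_r)` (ties: larger
#' window, then earlier position); maximizing the summed excess rather
#' than the mean alone keeps a coherent block together instead of
#' shrinking to its tightest corner. The chosen window is then trimmed:
#' a member whose mean correlation with the rest falls below the midpoint
#' between `min_mean_r` and the window's mean pairwise correlation is a
#' seriation neighbour rather than a cluster member and is dropped;
#' trimming repeats until stable. This is a deterministic stand-in for
#' marking the visually evident block on a sorted heatmap. A
#' user-supplied `override` list skips detection and simply scores that
#' cluster (useful to reproduce a cluster chosen by eye).
#'
#' @param cm A `correlation_matrix`.
#' @param min_size Minimum cluster size (>= 3).
#' @param min_mean_r Minimum mean pairwise correlation (default 0.5).
#' @param override Optional character vector: accept exactly these genes
#'   as the cluster (all must be present in `cm`).
#' @return An object of class `gene_cluster`: list with `genes`,
#'   `mean_pairwise_r`, `ordering` (the full seriated order) and `found`.
#'   When no window qualifies, `found` is `FALSE` and `genes` is empty —
#'   not an error.
#' @export
identify_cluster <- function(cm, min_size = 3, min_mean_r = 0.5,
                             override = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (min_size < 3) abort("min_size must be at least 3.")
  ord <- seriate_genes(cm)
  if (!is.null(override)) {
    override <- unique(override)
    missing <- setdiff(override, cm$genes)
    if (length(missing)) {
      abort(paste0("Override gene(s) not in the correlation matrix: ",
                   paste(missing, collapse = ", ")))
    }
    return(structure(list(genes = override,
                          mean_pairwise_r = mean_pairwise_r(cm, override),
                          ordering = ord, found = TRUE),
                     class = "gene_cluster"))
  }
  k <- length(ord)
  best <- NULL
  for (size in seq(min_size, k)) {
    for (start in seq_len(k - size + 1)) {
      win <- ord[start:(start + size - 1)]
      mr <- mean_pairwise_r(cm, win)
      if (mr < min_mean_r) next
      sc <- choose(size, 2) * (mr - min_mean_r)
      if (is.null(best) || sc > best$sc + 1e-12 ||
          (abs(sc - best$sc) <= 1e-12 && size > best$size)) {
        best <- list(genes = win, mr = mr, size = size, sc = sc)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(genes = character(0), mean_pairwise_r = NA_real_,
                          ordering = ord, found = FALSE),
                     class = "gene_cluster"))
  }
  genes <- best$genes
  repeat {
    if (length(genes) <= min_size) break
    sub <- cm$r[genes, genes, drop = FALSE]
    mr <- mean(sub[upper.tri(sub)])
    coherence <- (rowSums(sub) - 1) / (length(genes) - 1)
    cut <- (min_mean_r + mr) / 2
    if (min(coherence) >= cut) break
    genes <- genes[-which.min(coherence)]
  }
  mr <- mean_pairwise_r(cm, genes)
  if (mr < min_mean_r || length(genes) < min_size) {
    return(structure(list(genes = character(0), mean_pairwise_r = NA_real_,
                          ordering = ord, found = FALSE),
                     class = "gene_cluster"))
  }
  structure(list(genes = genes, mean_pairwise_r = mr,
                 ordering = ord, found = TRUE),
            class = "gene_cluster")
}

mean_pairwise_r <- function(cm, genes) {
  sub <- cm$r[genes, genes, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' @export
print.gene_cluster <- function(x, ...) {
  if (!x$found) {
    cat("<gene_cluster> no qualifying cluster\n")
  } else {
    cat(sprintf("<gene_cluster> %d genes, mean pairwise r = %.3f\n",
                length(x$genes), x$mean_pairwise_r))
    cat(" ", paste(x$genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Average expression profile of a gene cluster
#'
#' Each cluster gene is z-scored across the group's samples, then the
#' z-scores are averaged per sample. Standardizing first stops
#' high-variance genes from dominating the profile; set
#' `standardize = FALSE` for a plain mean. Zero-variance genes are dropped
#' with a warning.
#'
#' @param es An [expression_set()].
#' @param cluster A `gene_cluster` or a character vector of genes.
#' @param group `"case"` (default), `"control"` or `"all"`.
#' @param region Optional region label.
#' @param standardize Z-score genes before averaging (default `TRUE`).
#' @return A tibble with columns `sample_id`, `profile`.
#' @export
average_profile <- function(es, cluster, group = "case", region = NULL,
                            standardize = TRUE) {
  stopifnot(inherits(es, "expression_set"))
  genes <- if (inherits(cluster, "gene_cluster")) cluster$genes else cluster
  if (length(genes) == 0) abort("Cluster is empty.")
  missing <- setdiff(genes, rownames(es$values))
  if (length(missing)) {
    abort(paste0("Cluster gene(s) not in the matrix: ",
                 paste(missing, collapse = ", ")))
  }
  samples <- group_samples(es, group, region, min_n = 4)
  x <- es$values[genes, samples, drop = FALSE]
  if (standardize) {
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      warn(paste0("Dropping zero-variance cluster gene(s): ",
                  paste(genes[sds == 0], collapse = ", ")))
      x <- x[sds > 0, , drop = FALSE]
      if (nrow(x) == 0) abort("All cluster genes have zero variance.")
      sds <- sds[sds > 0]
    }
    x <- (x - rowMeans(x)) / sds
  }
  tibble(sample_id = samples, profile = colMeans(x))
}

#' Expand a seed cluster to a fixed-size gene list
#'
#' Ranks every gene in the matrix by its Pearson correlation (descending;
#' ties broken by gene name) with the cluster's average profile across the
#' group's samples, and returns the top `M` genes. Seed genes are always
#' retained, so the result contains the seed plus the best-correlated
#' other genes up to `M` in total. `min_r_attained` is the lowest profile
#' correlation among the selected members — an emergent property of the
#' data, not an input.
#'
#' @param es An [expression_set()].
#' @param cluster A `gene_cluster` (or character vector): the seed.
#' @param M Total size of the expanded list (>= seed size).
#' @param group,region,standardize As in [average_profile()].
#' @param profile Optional precomputed profile tibble (`sample_id`,
#'   `profile`); computed from the cluster when `NULL`.
#' @return An object of class `expanded_gene_list`: list with `seed`,
#'   `members` (tibble `gene`, `r_to_profile`, `is_seed`, sorted by
#'   descending correlation), `profile`, `min_r_attained`, `M`.
#' @export
expand_cluster <- function(es, cluster, M = 800, group = "case",
                           region = NULL, standardize = TRUE,
                           profile = NULL) {
  stopifnot(inherits(es, "expression_set"))
  seed_genes <- if (inherits(cluster, "gene_cluster")) cluster$genes
                else unique(cluster)
  if (length(seed_genes) == 0) abort("Seed cluster is empty.")
  if (M < length(seed_genes)) abort("M must be at least the seed size.")
  if (M > nrow(es$values)) abort("M exceeds the number of genes.")
  if (is.null(profile)) {
    profile <- average_profile(es, seed_genes, group = group,
                               region = region, standardize = standardize)
  }
  samples <- profile$sample_id
  x <- es$values[, samples, drop = FALSE]
  p <- profile$profile
  pz <- p - mean(p)
  pss <- sqrt(sum(pz^2))
  if (pss == 0) abort("Profile has zero variance.")
  z <- x - rowMeans(x)
  ss <- sqrt(rowSums(z^2))
  r <- as.numeric(z %*% pz) / (ss * pss)
  r[ss == 0] <- 0
  names(r) <- rownames(x)
  ranked <- names(r)[order(-r, names(r))]
  extra <- setdiff(ranked, seed_genes)
  members <- c(seed_genes, extra[seq_len(M - length(seed_genes))])
  out <- tibble(gene = members, r_to_profile = unname(r[members]),
                is_seed = members %in% seed_genes) |>
    dplyr::arrange(dplyr::desc(.data$r_to_profile), .data$gene)
  structure(list(seed = seed_genes, members = out, profile = profile,
                 min_r_attained = min(out$r_to_profile), M = as.integer(M),
                 group = group),
            class = "expanded_gene_list")
}

#' @export
print.expanded_gene_list <- function(x, ...) {
  cat(sprintf(
    "<expanded_gene_list> %d genes (seed %d + %d added), min r = %.3f\n",
    nrow(x$members), length(x$seed), nrow(x$members) - length(x$seed),
    x$min_r_attained))
  invisible(x)
}

#' @describeIn expand_cluster Member table as a tibble.
#' @param x An `expanded_gene_list`.
#' @param ... Unused.
#' @method tidy expanded_gene_list
#' @export
tidy.expanded_gene_list <- function(x, ...) x$members

#' Write an expanded gene list to disk
#'
#' Writes the members one-gene-per-line, a TSV of (gene, r_to_profile,
#' is_seed), and the profile TSV.
#'
#' @param x An `expanded_gene_list`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_expanded_list <- function(x, dir) {
  stopifnot(inherits(x, "expanded_gene_list"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genes = file.path(dir, "expanded_genes.txt"),
                table = file.path(dir, "expanded_genes.tsv"),
                profile = file.path(dir, "profile.tsv"))
  readr::write_lines(x$members$gene, paths$genes)
  readr::write_tsv(x$members, paths$table, progress = FALSE)
  readr::write_tsv(x$profile, paths$profile, progress = FALSE)
  invisible(paths)
}
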
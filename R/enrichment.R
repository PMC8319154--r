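#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability of observing an overlap of at least `k` genes
#' between a list of size `K` and a list of size `n` drawn from a universe
#' of `N` genes: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap.
#' @param K Size of the first list.
#' @param n Size of the second list.
#' @param N Universe size.
#' @return A one-row tibble with columns `k`, `K`, `n`, `N`, `p_upper`.
#' @export
#'
#' @examples
#' hypergeom_overlap(k = 2, K = 4, n = 3, N = 10)  # p = 1/3
hypergeom_overlap <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("k, K, n, N must be non-negative integers.")
  }
  if (K > N || n > N) abort("K and n must not exceed the universe size N.")
  if (k > min(K, n)) abort("k cannot exceed min(K, n).")
  if (k < max(0, K + n - N)) {
    abort("k is below the minimum possible overlap max(0, K + n - N).")
  }
  p <- phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  tibble(k = as.integer(k), K = as.integer(K), n = as.integer(n),
         N = as.integer(N), p_upper = p)
}

#' Over-representation analysis of a gene list against gene sets
#'
#' For each set, tests the overlap between the query list and the set
#' (both intersected with the universe) with the upper-tail hypergeometric
#' test, corrects across sets with Benjamini-Hochberg, and attaches the
#' enrichment score `-log2(p_adj)` plus a tier: `"high"` when
#' `p_adj <= 1e-4`, `"medium"` when `1e-4 < p_adj <= 0.05`, `"low"`
#' otherwise.
#'
#' @param genes Character vector: the query gene list.
#' @param sets A `gene_set_collection` (named list of character vectors).
#' @param universe Character vector of all testable genes. Query genes
#'   outside the universe are dropped with a warning; sets are intersected
#'   with the universe and empty intersections are not tested.
#' @return A tibble with one row per tested set: `set_name`, `k`,
#'   `set_size`, `list_size`, `universe_size`, `p`, `p_adj`, `score`,
#'   `tier`, `overlap_genes` (list-column), sorted by `p_adj` then name.
#' @export
ora <- function(genes, sets, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (length(universe) == 0) abort("Universe is empty.")
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped.",
                 length(outside)))
    genes <- intersect(genes, universe)
  }
  if (length(genes) == 0) abort("No query genes left in the universe.")
  if (length(sets) == 0 || is.null(names(sets))) {
    abort("`sets` must be a non-empty named list.")
  }
  rows <- purrr::imap(sets, function(members, nm) {
    in_univ <- intersect(unique(members), universe)
    if (length(in_univ) == 0) return(NULL)
    ov <- intersect(genes, in_univ)
    tibble(set_name = nm, k = length(ov), set_size = length(in_univ),
           list_size = length(genes), universe_size = length(universe),
           p = hypergeom_overlap(length(ov), length(genes),
                                 length(in_univ), length(universe))$p_upper,
           overlap_genes = list(sort(ov)))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) abort("No set intersects the universe.")
  res |>
    dplyr::mutate(p_adj = p.adjust(.data$p, method = "BH"),
                  score = -log2(.data$p_adj),
                  tier = enrichment_tier(.data$p_adj)) |>
    dplyr::arrange(.data$p_adj, .data$set_name) |>
    dplyr::relocate("overlap_genes", .after = "tier")
}

enrichment_tier <- function(p_adj) {
  dplyr::case_when(p_adj <= 1e-4 ~ "high",
                   p_adj <= 0.05 ~ "medium",
                   TRUE ~ "low")
}

#' Overlap of two enrichment results
#'
#' Tests whether the sets called enriched (`p_adj <= alpha`) in two
#' analyses overlap more than expected by chance, given a stated universe
#' of testable sets.
#'
#' @param rows_a,rows_b Tibbles from [ora()].
#' @param universe_size Number of testable sets the two analyses drew from.
#' @param alpha Enrichment cutoff on `p_adj` (default 0.05).
#' @return A one-row tibble: `k`, `K`, `n`, `N`, `p_upper`,
#'   `overlap_sets` (list-column of shared set names).
#' @export
overlap_of_enrichments <- function(rows_a, rows_b, universe_size,
                                   alpha = 0.05) {
  enr_a <- rows_a$set_name[rows_a$p_adj <= alpha]
  enr_b <- rows_b$set_name[rows_b$p_adj <= alpha]
  if (universe_size < length(union(enr_a, enr_b))) {
    abort("Universe smaller than the union of enriched sets.")
  }
  shared <- intersect(enr_a, enr_b)
  out <- hypergeom_overlap(length(shared), length(enr_a), length(enr_b),
                           universe_size)
  out$overlap_sets <- list(sort(shared))
  out
}

#' Write enrichment results as TSV (and optionally JSON)
#'
#' @param rows A tibble from [ora()].
#' @param path Output TSV path.
#' @param json_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path, json_path = NULL) {
  flat <- rows |>
    dplyr::mutate(overlap_genes = purrr::map_chr(
      .data$overlap_genes, paste, collapse = ","))
  readr::write_tsv(flat, path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
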
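#' Per-gene case-vs-control t-statistics
#'
#' Computes a pooled-variance (Student) two-sample t-statistic per gene,
#' comparing case and control samples, optionally within one region. Genes
#' with zero pooled variance get t = 0 and are flagged.
#'
#' @param es An [expression_set()].
#' @param region Optional region label.
#' @param welch Use Welch's unequal-variance statistic instead of the
#'   pooled one (default `FALSE`).
#' @return A tibble with columns `gene_id`, `t`, `flagged`; attributes
#'   `n_case`, `n_ctrl`, `region`.
#' @export
gene_t_stats <- function(es, region = NULL, welch = FALSE) {
  stopifnot(inherits(es, "expression_set"))
  case_ids <- group_samples(es, "case", region, min_n = 3)
  ctrl_ids <- group_samples(es, "control", region, min_n = 3)
  xc <- es$values[, case_ids, drop = FALSE]
  xk <- es$values[, ctrl_ids, drop = FALSE]
  n1 <- length(case_ids); n2 <- length(ctrl_ids)
  m1 <- rowMeans(xc); m2 <- rowMeans(xk)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xk - m2)^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t <- unname((m1 - m2) / se)
  flagged <- !is.finite(t)
  t[flagged] <- 0
  out <- tibble(gene_id = rownames(es$values), t = t, flagged = flagged)
  attr(out, "n_case") <- n1
  attr(out, "n_ctrl") <- n2
  attr(out, "region") <- region
  out
}

#' Pairwise comparability of datasets/regions from t-statistic vectors
#'
#' For every unordered pair of t-statistic vectors, computes the Pearson
#' correlation `rho` over the genes shared by the two vectors, a two-sided
#' p-value from the t transform at `n_shared - 2` degrees of freedom, and
#' the comparability flag `rho > 0.1 & p < 0.001`.
#'
#' @param tstats Named list of tibbles from [gene_t_stats()] (names label
#'   the regions/datasets).
#' @param rho_min,p_max Comparability rule (defaults 0.1 and 0.001).
#' @return A tibble with one row per pair: `region_a`, `region_b`, `rho`,
#'   `p`, `n_shared`, `comparable`.
#' @export
comparability_matrix <- function(tstats, rho_min = 0.1, p_max = 0.001) {
  if (length(tstats) < 2) abort("Need at least 2 t-statistic vectors.")
  if (is.null(names(tstats)) || any(!nzchar(names(tstats)))) {
    abort("`tstats` must be a named list.")
  }
  nms <- names(tstats)
  pairs <- utils::combn(nms, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- tstats[[pairs[1, i]]]; b <- tstats[[pairs[2, i]]]
    shared <- intersect(a$gene_id, b$gene_id)
    if (length(shared) == 0) abort(
      sprintf("No shared genes between %s and %s.", pairs[1, i], pairs[2, i]))
    if (length(shared) < 100) {
      warn(sprintf("Only %d shared genes between %s and %s.",
                   length(shared), pairs[1, i], pairs[2, i]))
    }
    ta <- a$t[match(shared, a$gene_id)]
    tb <- b$t[match(shared, b$gene_id)]
    rho <- suppressWarnings(cor(ta, tb))
    if (is.na(rho)) rho <- 0
    p <- if (length(shared) > 2) corr_p_value(rho, length(shared)) else 1
    tibble(region_a = pairs[1, i], region_b = pairs[2, i], rho = rho,
           p = p, n_shared = length(shared),
           comparable = rho > rho_min & p < p_max)
  })
  dplyr::bind_rows(rows)
}
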
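#' Pairwise Pearson correlation of a gene list within one diagnosis group
#'
#' Computes the Pearson correlation matrix of the listed genes across the
#' samples of one diagnosis group (optionally one region), together with
#' per-pair two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#' Listed genes absent from the matrix are dropped with a warning. A gene
#' with zero variance in the group yields r = 0 for all its pairs and is
#' flagged rather than raising an error.
#'
#' @param es An [expression_set()].
#' @param genes Character vector of gene symbols.
#' @param group `"case"` (default), `"control"` or `"all"`.
#' @param region Optional region label.
#' @return An object of class `correlation_matrix`: list with `genes`,
#'   `r` (symmetric matrix), `p` (matrix), `n_samples`, `group`,
#'   `zero_variance` (flagged genes).
#' @export
pairwise_correlation <- function(es, genes, group = "case", region = NULL) {
  stopifnot(inherits(es, "expression_set"))
  samples <- group_samples(es, group, region, min_n = 4)
  genes <- unique(genes)
  present <- genes[genes %in% rownames(es$values)]
  absent <- setdiff(genes, present)
  if (length(absent)) {
    warn(sprintf("%d listed gene(s) absent from the matrix: %s",
                 length(absent),
                 paste(head(absent, 10), collapse = ", ")))
  }
  if (length(present) < 2) abort("Need at least 2 listed genes in the matrix.")
  x <- t(es$values[present, samples, drop = FALSE])
  sds <- apply(x, 2, sd)
  zero_var <- colnames(x)[sds == 0]
  r <- suppressWarnings(cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  n <- length(samples)
  p <- corr_p_value(r, n)
  diag(p) <- 0
  if (length(zero_var)) {
    warn(paste0("Zero-variance gene(s), pairs set to r = 0: ",
                paste(zero_var, collapse = ", ")))
    p[zero_var, ] <- 1
    p[, zero_var] <- 1
    diag(p) <- 0
  }
  structure(list(genes = present, r = r, p = p, n_samples = n,
                 group = group, region = region, zero_variance = zero_var),
            class = "correlation_matrix")
}

# two-sided p for Pearson r at given sample size, via the t transform
corr_p_value <- function(r, n) {
  df <- n - 2
  r2 <- pmin(abs(r), 1 - 1e-15)
  tval <- r2 * sqrt(df / (1 - r2^2))
  2 * pt(tval, df, lower.tail = FALSE)
}

# |r| threshold equivalent to a two-sided per-pair level alpha
critical_r <- function(alpha, n) {
  df <- n - 2
  tcrit <- qt(1 - alpha / 2, df)
  tcrit / sqrt(tcrit^2 + df)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf(
    "<correlation_matrix> %d genes, %d '%s' samples%s\n",
    length(x$genes), x$n_samples, x$group,
    if (is.null(x$region)) "" else paste0(" (region ", x$region, ")")))
  invisible(x)
}

#' Tidy a correlation matrix into one row per unordered gene pair
#'
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_a`, `gene_b`, `r`, `p`.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  k <- length(x$genes)
  ut <- upper.tri(x$r)
  idx <- which(ut, arr.ind = TRUE)
  tibble(gene_a = x$genes[idx[, 1]], gene_b = x$genes[idx[, 2]],
         r = x$r[ut], p = x$p[ut])
}

#' Count significantly correlated gene pairs
#'
#' Counts unordered off-diagonal pairs that pass a threshold: in mode
#' `"alpha"`, pairs whose two-sided correlation p-value is below `value`;
#' in mode `"abs_r"`, pairs with `|r| > value`.
#'
#' @param cm A `correlation_matrix`.
#' @param mode `"alpha"` (default) or `"abs_r"`.
#' @param value Threshold in (0, 1); default 0.05.
#' @return Integer count.
#' @export
count_significant_pairs <- function(cm, mode = c("alpha", "abs_r"),
                                    value = 0.05) {
  stopifnot(inherits(cm, "correlation_matrix"))
  mode <- match.arg(mode)
  if (!is.numeric(value) || value <= 0 || value >= 1) {
    abort("`value` must lie strictly in (0, 1).")
  }
  ut <- upper.tri(cm$r)
  if (mode == "alpha") {
    sum(cm$p[ut] < value)
  } else {
    sum(abs(cm$r[ut]) > value)
  }
}

#' Permutation test for a correlation pattern
#'
#' Assesses whether a gene list is more mutually correlated than random
#' gene groups of the same size: the observed statistic is the number of
#' significantly correlated pairs (see [count_significant_pairs()]); the
#' null is built by drawing `B` random gene groups (uniformly, without
#' replacement, from all genes in the matrix) and recomputing the count.
#' The empirical p-value is the fraction of null counts at least as large
#' as the observed count; the conservative variant `(b + 1)/(B + 1)` is
#' reported alongside.
#'
#' @inheritParams pairwise_correlation
#' @inheritParams count_significant_pairs
#' @param B Number of random groups (>= 100; default 1000).
#' @param seed Optional integer seed for the random draws.
#' @return An object of class `perm_pattern_test` with fields
#'   `observed_count`, `null_counts`, `B`, `threshold_mode`,
#'   `threshold_value`, `empirical_p`, `empirical_p_conservative`,
#'   `n_genes`, `n_samples`, `group`, `seed`.
#' @export
permutation_pattern_test <- function(es, genes, group = "case",
                                     mode = c("alpha", "abs_r"),
                                     value = 0.05, B = 1000, seed = NULL,
                                     region = NULL) {
  stopifnot(inherits(es, "expression_set"))
  mode <- match.arg(mode)
  if (B < 100) abort("B must be at least 100.")
  if (!is.numeric(value) || value <= 0 || value >= 1) {
    abort("`value` must lie strictly in (0, 1).")
  }
  samples <- group_samples(es, group, region, min_n = 4)
  genes <- unique(genes)
  present <- sort(genes[genes %in% rownames(es$values)])
  if (length(present) < 2) abort("Need at least 2 listed genes in the matrix.")
  universe <- rownames(es$values)
  k <- length(present)
  if (length(universe) < 2 * k) {
    abort("Gene universe must be at least twice the group size.")
  }
  n <- length(samples)
  thr <- if (mode == "alpha") critical_r(value, n) else value

  # rows standardized to unit sum of squares: r = tcrossprod(z)
  x <- es$values[, samples, drop = FALSE]
  z <- x - rowMeans(x)
  ss <- sqrt(rowSums(z^2))
  ok <- ss > 0
  z[ok, ] <- z[ok, , drop = FALSE] / ss[ok]
  z[!ok, ] <- 0  # zero-variance genes contribute r = 0 pairs

  count_pairs <- function(ids) {
    r <- tcrossprod(z[ids, , drop = FALSE])
    sum(abs(r[upper.tri(r)]) > thr)
  }
  b0 <- count_pairs(present)
  if (!is.null(seed)) set.seed(seed)
  null_counts <- vapply(seq_len(B), function(i) {
    count_pairs(sample(universe, k))
  }, numeric(1))
  b <- sum(null_counts >= b0)
  structure(list(observed_count = as.integer(b0),
                 null_counts = as.integer(null_counts), B = as.integer(B),
                 threshold_mode = mode, threshold_value = value,
                 empirical_p = b / B,
                 empirical_p_conservative = (b + 1) / (B + 1),
                 n_genes = k, n_samples = n, group = group,
                 region = region, seed = seed),
            class = "perm_pattern_test")
}

#' @export
print.perm_pattern_test <- function(x, ...) {
  cat(sprintf(
    paste0("<perm_pattern_test> %d genes, %d samples (%s)\n",
           "  observed significant pairs: %d (mode %s, value %g)\n",
           "  empirical p = %.4g (B = %d; conservative %.4g)\n"),
    x$n_genes, x$n_samples, x$group, x$observed_count, x$threshold_mode,
    x$threshold_value, x$empirical_p, x$B, x$empirical_p_conservative))
  invisible(x)
}

#' @describeIn permutation_pattern_test One row per null draw
#'   (`draw`, `null_count`).
#' @param x A `perm_pattern_test`.
#' @param ... Unused.
#' @method tidy perm_pattern_test
#' @export
tidy.perm_pattern_test <- function(x, ...) {
  tibble(draw = seq_len(x$B), null_count = x$null_counts)
}

#' @describeIn permutation_pattern_test One-row summary tibble.
#' @method glance perm_pattern_test
#' @export
glance.perm_pattern_test <- function(x, ...) {
  tibble(observed_count = x$observed_count, B = x$B,
         threshold_mode = x$threshold_mode,
         threshold_value = x$threshold_value,
         empirical_p = x$empirical_p,
         empirical_p_conservative = x$empirical_p_conservative,
         n_genes = x$n_genes, n_samples = x$n_samples, group = x$group)
}

#' Write permutation-test results as JSON
#'
#' @param x A `perm_pattern_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perm_test_json <- function(x, path) {
  stopifnot(inherits(x, "perm_pattern_test"))
  jsonlite::write_json(
    list(observed_count = x$observed_count, null_counts = x$null_counts,
         B = x$B, threshold_mode = x$threshold_mode,
         threshold_value = x$threshold_value, empirical_p = x$empirical_p,
         empirical_p_conservative = x$empirical_p_conservative,
         n_genes = x$n_genes, n_samples = x$n_samples, group = x$group,
         seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
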
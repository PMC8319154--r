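#' Configuration for the synthetic expression generator
#'
#' The generator emulates the structure of a post-mortem brain microarray
#' case/control dataset: a modest number of case and control samples, a
#' small planted block of mutually correlated "GWAS" genes driven by one
#' latent factor, a larger pool of genes loading on the same factor, and a
#' pathway whose genes carry a small case-vs-control mean shift that is
#' individually non-significant but collectively directional.
#'
#' Defaults mirror the hippocampus arm of the study design the package is
#' built around: 16 case and 18 control samples, a 7-gene cluster with
#' loading 0.9, a 100-gene pool with loadings uniform on [0.6, 0.95], and
#' an 18-gene pathway with a shift of half a control standard deviation.
#'
#' @param n_genes Total number of genes.
#' @param n_case,n_ctrl Case and control sample counts.
#' @param cluster_genes Size k of the planted co-expressed cluster.
#' @param cluster_loading Loading lambda in [0, 1] of cluster genes on the
#'   latent factor; the expected pairwise correlation is lambda^2.
#' @param pool_genes Number of additional genes loading on the factor.
#' @param pool_loading_range Two values in [0, 1]: pool loadings are drawn
#'   uniformly from this range.
#' @param pathway_genes Number of genes in the planted pathway.
#' @param effect_size Case-minus-control mean shift of pathway genes, in
#'   units of the per-gene noise SD (delta).
#' @param noise_sd Residual SD sigma (default 1, so loadings map directly
#'   to expected correlations).
#' @param region,dataset Labels stored in the sample metadata.
#' @param seed Integer seed; the same config always yields the same data.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 10000, n_case = 16, n_ctrl = 18,
                             cluster_genes = 7, cluster_loading = 0.9,
                             pool_genes = 100,
                             pool_loading_range = c(0.6, 0.95),
                             pathway_genes = 18, effect_size = 0.5,
                             noise_sd = 1, region = "RG1",
                             dataset = "SYN1", seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_ctrl = as.integer(n_ctrl),
              cluster_genes = as.integer(cluster_genes),
              cluster_loading = cluster_loading,
              pool_genes = as.integer(pool_genes),
              pool_loading_range = pool_loading_range,
              pathway_genes = as.integer(pathway_genes),
              effect_size = effect_size, noise_sd = noise_sd,
              region = region, dataset = dataset, seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_case, cfg$n_ctrl, cfg$cluster_genes,
              cfg$pool_genes, cfg$pathway_genes)
  if (any(is.na(counts)) || any(counts < 0) ||
      cfg$n_genes <= 0 || cfg$n_case <= 0 || cfg$n_ctrl <= 0) {
    abort("Counts must be positive (planted group sizes may be zero).")
  }
  if (cfg$cluster_genes + cfg$pool_genes + cfg$pathway_genes > cfg$n_genes) {
    abort("cluster_genes + pool_genes + pathway_genes must be <= n_genes.")
  }
  lam <- c(cfg$cluster_loading, cfg$pool_loading_range)
  if (any(lam < 0 | lam > 1)) abort("Loadings must lie in [0, 1].")
  if (diff(cfg$pool_loading_range) < 0) {
    abort("pool_loading_range must be increasing.")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be positive.")
  structure(cfg, class = "synthetic_config")
}

#' Simulate an expression dataset with planted structure
#'
#' Per sample s a latent factor f_s ~ N(0, 1) is drawn. A cluster or pool
#' gene g with loading lambda_g has
#' `x_gs = mu_g + lambda_g * f_s + sqrt(1 - lambda_g^2) * e_gs`,
#' `e ~ N(0, sigma)`; with sigma = 1 the expected correlation of two such
#' genes is the product of their loadings. A pathway gene has
#' `x_gs = mu_g + delta * sigma * [s is case] + sigma * e_gs`; background
#' genes are independent `N(mu_g, sigma)`. Baselines `mu_g ~ N(8, 1)`
#' mimic log2 microarray intensities.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `expression` (an [expression_set()]) and
#'   `truth` (class `synthetic_truth`): `cluster`, `pool`, `pathway` gene
#'   ids, `pool_loadings`, per-gene `true_shift`, and the latent `factor`
#'   per sample.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_ctrl
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n))
  diagnosis <- c(rep("case", cfg$n_case), rep("control", cfg$n_ctrl))

  shuffled <- sample(gene_ids)
  idx <- 0L
  take <- function(k) {
    out <- shuffled[seq_len(k) + idx]
    idx <<- idx + k
    sort(out)
  }
  cluster <- take(cfg$cluster_genes)
  pool <- take(cfg$pool_genes)
  pathway <- take(cfg$pathway_genes)

  mu <- rnorm(cfg$n_genes, mean = 8, sd = 1)
  names(mu) <- gene_ids
  f <- rnorm(n)
  sigma <- cfg$noise_sd

  values <- matrix(rnorm(cfg$n_genes * n, sd = sigma), cfg$n_genes, n,
                   dimnames = list(gene_ids, sample_ids))

  loadings <- setNames(numeric(0), character(0))
  if (length(cluster)) {
    loadings[cluster] <- cfg$cluster_loading
  }
  pool_load <- runif(length(pool), cfg$pool_loading_range[1],
                     cfg$pool_loading_range[2])
  if (length(pool)) loadings[pool] <- pool_load
  for (g in names(loadings)) {
    lam <- loadings[[g]]
    values[g, ] <- lam * f + sqrt(1 - lam^2) * values[g, ]
  }
  true_shift <- setNames(rep(0, cfg$n_genes), gene_ids)
  if (length(pathway)) {
    true_shift[pathway] <- cfg$effect_size * sigma
    values[pathway, diagnosis == "case"] <-
      values[pathway, diagnosis == "case"] + cfg$effect_size * sigma
  }
  values <- values + mu

  md <- tibble(sample_id = sample_ids, diagnosis = diagnosis,
               region = cfg$region, dataset = cfg$dataset)
  truth <- structure(
    list(cluster = cluster, pool = pool, pathway = pathway,
         pool_loadings = setNames(pool_load, pool),
         true_shift = true_shift,
         factor = setNames(f, sample_ids),
         background = setdiff(gene_ids, c(cluster, pool, pathway))),
    class = "synthetic_truth")
  list(expression = expression_set(values, md), truth = truth)
}

#' Simulate a gene-set collection with the planted pathway plus decoys
#'
#' @param truth A `synthetic_truth` from [simulate_expression()].
#' @param n_decoy_sets Number of decoy sets (default 50).
#' @param size_range Decoy sizes are drawn uniformly from this integer
#'   range (default 10 to 100).
#' @param seed Integer seed.
#' @return A `gene_set_collection`: the set `"planted_pathway"` (exactly
#'   the planted pathway genes) plus decoys drawn from background genes.
#' @export
simulate_gene_sets <- function(truth, n_decoy_sets = 50,
                               size_range = c(10, 100), seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  bg <- truth$background
  if (max(size_range) > length(bg)) {
    abort("Requested decoy size exceeds available background genes.")
  }
  sets <- list(planted_pathway = truth$pathway)
  if (n_decoy_sets > 0) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_decoy_sets,
                    replace = TRUE)
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("decoy_%03d", i)]] <- sort(sample(bg, sizes[i]))
    }
  }
  structure(sets, class = "gene_set_collection", source = "synthetic")
}

#' Simulate a STRING-style co-expression edge table
#'
#' Pathway-gene pairs are connected with probability `p_within` (scores
#' uniform on [0.4, 1]); pairs involving a background subset are connected
#' with probability `p_background` (scores uniform on [0.1, 0.4]).
#'
#' @param truth A `synthetic_truth`.
#' @param p_within Within-pathway edge probability.
#' @param p_background Background edge probability.
#' @param n_background_genes Size of the background gene subset that takes
#'   part in background edges (default 100; keeps the table small).
#' @param seed Integer seed.
#' @return An edge tibble (`gene_a`, `gene_b`, `score`), undirected with
#'   no self-edges.
#' @export
simulate_edges <- function(truth, p_within = 0.8, p_background = 0.02,
                           n_background_genes = 100, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (p_within < 0 || p_within > 1 || p_background < 0 || p_background > 1) {
    abort("Edge probabilities must lie in [0, 1].")
  }
  set.seed(seed)
  pw <- truth$pathway
  bg <- truth$background
  bg_sub <- sort(sample(bg, min(n_background_genes, length(bg))))
  pair_edges <- function(genes_a, genes_b = NULL, p, lo, hi) {
    if (is.null(genes_b)) {
      if (length(genes_a) < 2) return(NULL)
      pairs <- t(utils::combn(genes_a, 2))
    } else {
      pairs <- as.matrix(expand.grid(genes_a, genes_b,
                                     stringsAsFactors = FALSE))
      pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    }
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) return(NULL)
    pairs <- pairs[keep, , drop = FALSE]
    tibble(gene_a = pairs[, 1], gene_b = pairs[, 2],
           score = runif(nrow(pairs), lo, hi))
  }
  edges <- dplyr::bind_rows(
    pair_edges(pw, p = p_within, lo = 0.4, hi = 1.0),
    pair_edges(bg_sub, p = p_background, lo = 0.1, hi = 0.4),
    pair_edges(pw, bg_sub, p = p_background, lo = 0.1, hi = 0.4))
  if (is.null(edges) || nrow(edges) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  score = numeric()))
  }
  normalize_edges(edges)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix, metadata, gene sets (GMT), edge table and
#' the ground truth (JSON) in the formats the readers in this package
#' accept.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param n_decoy_sets,p_within,p_background Passed to the set/edge
#'   simulators.
#' @param size_range Decoy set sizes; by default 10 to 100, capped at the
#'   number of available background genes.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_dataset <- function(cfg, dir, n_decoy_sets = 50, p_within = 0.8,
                             p_background = 0.02, size_range = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(cfg)
  if (is.null(size_range)) {
    nbg <- length(sim$truth$background)
    size_range <- c(min(10, nbg), min(100, nbg))
  }
  sets <- simulate_gene_sets(sim$truth, n_decoy_sets = n_decoy_sets,
                             size_range = size_range,
                             seed = cfg$seed + 1L)
  edges <- simulate_edges(sim$truth, p_within = p_within,
                          p_background = p_background,
                          seed = cfg$seed + 2L)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    edges = file.path(dir, "edges.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression(sim$expression, paths$expression, paths$metadata)
  write_gmt(sets, paths$gene_sets)
  readr::write_tsv(edges, paths$edges, progress = FALSE)
  jsonlite::write_json(
    list(cluster = sim$truth$cluster, pool = sim$truth$pool,
         pathway = sim$truth$pathway,
         pool_loadings = as.list(sim$truth$pool_loadings),
         effect_size = cfg$effect_size, seed = cfg$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
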
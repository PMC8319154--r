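#' Read a pipeline run configuration
#'
#' Accepts either a YAML file or a flat `key=value` file (one pair per
#' line, `#` comments allowed). Numeric-looking values are converted to
#' numbers.
#'
#' @param path Config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(body) && all(grepl("=", body, fixed = TRUE)) &&
      !any(grepl(":", body, fixed = TRUE))) {
    kv <- strsplit(body, "=", fixed = TRUE)
    cfg <- lapply(kv, function(x) trimws(paste(x[-1], collapse = "=")))
    names(cfg) <- vapply(kv, function(x) trimws(x[1]), character(1))
    cfg <- lapply(cfg, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    cfg
  } else {
    yaml::read_yaml(path)
  }
}

default_run_config <- function() {
  list(group = "case", region = NULL, B = 1000,
       threshold_mode = "alpha", threshold_value = 0.05,
       cluster_min_size = 3, cluster_min_mean_r = 0.5,
       cluster_override = NULL, M = 800, edge_min_score = 0.1,
       enrichment_alpha = 0.05, pathway_set = NULL, seed = 1L)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: correlation-pattern permutation test on the GWAS
#' gene list, cluster identification and expansion, over-representation
#' analysis of the expanded list, cross-region comparability (when the
#' metadata contains at least two regions), and pathway-level differential
#' expression (deviation scores, co-expression network, directional
#' binomial test) on the selected pathway. All outputs plus a
#' reproducibility manifest are written under `out_dir`; given the same
#' config and seed the result files are byte-identical across runs.
#'
#' @param config Named list (or path to a config file readable by
#'   [read_run_config()]). Required fields: `expression`, `metadata`,
#'   `gene_list`, `gene_sets`, `edges` (input paths) and `out_dir`.
#'   Optional fields with defaults: `group` ("case"), `region` (NULL),
#'   `B` (1000), `threshold_mode` ("alpha"), `threshold_value` (0.05),
#'   `cluster_min_size` (3), `cluster_min_mean_r` (0.5),
#'   `cluster_override` (NULL), `M` (800), `edge_min_score` (0.1),
#'   `enrichment_alpha` (0.05), `pathway_set` (NULL; defaults to the top
#'   enriched set), `seed` (1).
#' @return Invisibly, a list with the per-stage results (`corr_pattern`,
#'   `cluster`, `expansion`, `enrichment`, `comparability`, `pathway_de`)
#'   and `out_dir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  required <- c("expression", "metadata", "gene_list", "gene_sets",
                "edges", "out_dir")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) {
    abort(paste0("Config missing field(s): ", paste(miss, collapse = ", ")))
  }
  for (f in c("expression", "metadata", "gene_list", "gene_sets", "edges")) {
    if (!file.exists(cfg[[f]])) {
      abort(sprintf("Config file for '%s' does not exist: %s", f, cfg[[f]]))
    }
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  summaries <- list()

  es <- run_stage("expression_io", {
    read_expression(cfg$expression, cfg$metadata)
  })
  gwas_genes <- run_stage("expression_io", read_gene_list(cfg$gene_list))
  sets <- run_stage("expression_io", read_gmt(cfg$gene_sets))
  edges <- run_stage("expression_io", read_edges(cfg$edges))
  summaries$inputs <- list(n_genes = nrow(es$values),
                           n_samples = ncol(es$values),
                           n_listed_genes = length(gwas_genes),
                           n_sets = length(sets), n_edges = nrow(edges))

  region <- cfg$region %||% NULL
  pt <- run_stage("corr_pattern", {
    permutation_pattern_test(es, gwas_genes, group = cfg$group,
                             mode = cfg$threshold_mode,
                             value = cfg$threshold_value,
                             B = as.integer(cfg$B), seed = seed,
                             region = region)
  })
  write_perm_test_json(pt, file.path(out_dir, "corr_pattern.json"))
  summaries$corr_pattern <- list(observed_count = pt$observed_count,
                                 empirical_p = pt$empirical_p,
                                 B = pt$B)

  cm <- run_stage("corr_pattern", {
    suppressWarnings(pairwise_correlation(es, gwas_genes,
                                          group = cfg$group,
                                          region = region))
  })
  cl <- run_stage("cluster_expand", {
    identify_cluster(cm, min_size = as.integer(cfg$cluster_min_size),
                     min_mean_r = cfg$cluster_min_mean_r,
                     override = cfg$cluster_override)
  })
  expansion <- NULL
  enrich <- NULL
  if (!cl$found) {
    inform("No qualifying cluster; expansion and enrichment skipped.")
    summaries$cluster <- list(found = FALSE)
  } else {
    summaries$cluster <- list(found = TRUE, genes = cl$genes,
                              mean_pairwise_r = cl$mean_pairwise_r)
    expansion <- run_stage("cluster_expand", {
      expand_cluster(es, cl, M = as.integer(cfg$M), group = cfg$group,
                     region = region)
    })
    write_expanded_list(expansion, out_dir)
    summaries$expansion <- list(M = expansion$M,
                                min_r_attained = expansion$min_r_attained)
    enrich <- run_stage("enrichment", {
      ora(expansion$members$gene, sets, universe = rownames(es$values))
    })
    write_enrichment(enrich, file.path(out_dir, "enrichment.tsv"),
                     file.path(out_dir, "enrichment.json"))
    summaries$enrichment <- list(
      n_tested = nrow(enrich),
      n_enriched = sum(enrich$p_adj <= cfg$enrichment_alpha),
      top_set = enrich$set_name[1], top_p_adj = enrich$p_adj[1])
  }

  comp <- NULL
  regions <- unique(es$metadata$region)
  if (length(regions) >= 2) {
    comp <- run_stage("comparability", {
      tstats <- lapply(setNames(regions, regions),
                       function(rg) gene_t_stats(es, region = rg))
      comparability_matrix(tstats)
    })
    readr::write_tsv(comp, file.path(out_dir, "comparability.tsv"),
                     progress = FALSE)
    summaries$comparability <- list(n_pairs = nrow(comp),
                                    n_comparable = sum(comp$comparable))
  } else {
    inform("Only one region in the metadata; comparability stage skipped.")
    summaries$comparability <- list(skipped = TRUE)
  }

  pde <- NULL
  pathway_set <- cfg$pathway_set
  if (is.null(pathway_set) && !is.null(enrich)) {
    sig <- enrich$set_name[enrich$p_adj <= cfg$enrichment_alpha]
    if (length(sig)) pathway_set <- sig[1]
  }
  if (is.null(pathway_set)) {
    inform("No pathway selected (none enriched); pathway DE skipped.")
    summaries$pathway_de <- list(skipped = TRUE)
  } else {
    pde <- run_stage("pathway_de", {
      if (!pathway_set %in% names(sets)) {
        abort(sprintf("Pathway set '%s' not in the collection.",
                      pathway_set))
      }
      pw_genes <- intersect(sets[[pathway_set]], rownames(es$values))
      scores <- suppressWarnings(
        deviation_scores(es, pw_genes, region = region))
      net <- build_network(scores, edges,
                           min_score = cfg$edge_min_score,
                           pathway_name = pathway_set)
      tt <- tendency_test(scores)
      list(scores = scores, network = net, tendency = tt)
    })
    readr::write_tsv(pde$scores, file.path(out_dir, "deviation_scores.tsv"),
                     progress = FALSE)
    write_network(pde$network,
                  graphml_path = file.path(out_dir, "network.graphml"),
                  tsv_path = file.path(out_dir, "network_edges.tsv"))
    jsonlite::write_json(glance(pde$tendency),
                         file.path(out_dir, "tendency.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summaries$pathway_de <- list(
      pathway = pathway_set, n_scored = nrow(pde$scores),
      n_network_genes = nrow(pde$network$nodes),
      n_pos = pde$tendency$n_pos, n_neg = pde$tendency$n_neg,
      direction = pde$tendency$direction,
      p_binomial = pde$tendency$p_one_sided)
  }

  settings <- cfg[setdiff(names(cfg), c("cluster_override", "out_dir"))]
  settings <- settings[order(names(settings))]
  manifest <- list(
    package = "coexpand",
    version = as.character(utils::packageVersion("coexpand")),
    seed = seed, settings = settings, stages = summaries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  jsonlite::write_json(summaries, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(corr_pattern = pt, cluster = cl, expansion = expansion,
                 enrichment = enrich, comparability = comp,
                 pathway_de = pde, out_dir = out_dir,
                 summaries = summaries))
}
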
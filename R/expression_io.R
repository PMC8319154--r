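#' Read an expression matrix and its sample metadata
#'
#' Reads a tab-separated genes x samples table (header row of sample ids,
#' first column gene/probe ids) together with a metadata table
#' (`sample_id`, `diagnosis`, `region`, `dataset`). Values are assumed to be
#' on the log2 intensity scale; with `log2_transform = "auto"` a
#' `log2(x + 1)` transform is applied when the maximum value exceeds 50,
#' which flags data still on the linear scale. Gzipped files are accepted.
#'
#' @param path Expression TSV (genes in rows, samples in columns).
#' @param metadata_path Metadata TSV with columns `sample_id`, `diagnosis`,
#'   `region`, `dataset`.
#' @param log2_transform `"auto"` (default; transform when max > 50),
#'   `"yes"` (always `log2(x + 1)`) or `"no"`.
#' @return An [expression_set()].
#' @export
read_expression <- function(path, metadata_path,
                            log2_transform = c("auto", "yes", "no")) {
  log2_transform <- match.arg(log2_transform)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) abort("Expression file needs an id column plus samples.")
  sample_ids <- names(raw)[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    abort(paste0("Duplicated sample column(s): ", paste(dup, collapse = ", ")))
  }
  gene_ids <- raw[[1]]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    abort(paste0("Duplicated gene/probe row(s): ",
                 paste(dup_g, collapse = ", ")))
  }
  values <- matrix(NA_real_, nrow(raw), length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric value '%s' at line %d (gene %s, sample %s) in %s.",
        col[bad[1]], bad[1] + 1L, gene_ids[bad[1]], sample_ids[j], path))
    }
    if (anyNA(num)) {
      abort(sprintf("Missing value for gene %s, sample %s in %s.",
                    gene_ids[which(is.na(num))[1]], sample_ids[j], path))
    }
    values[, j] <- num
  }
  metadata <- readr::read_tsv(metadata_path, progress = FALSE,
                              col_types = readr::cols(.default = "c"))
  if (log2_transform == "yes" ||
      (log2_transform == "auto" && max(values) > 50)) {
    if (any(values < 0)) {
      abort("Cannot log2-transform: negative values present.")
    }
    values <- log2(values + 1)
    inform("Applied log2(x + 1) transform (values looked linear-scale).")
  }
  expression_set(values, metadata)
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression()]: values round-trip to at least six
#' decimals.
#'
#' @param es An [expression_set()].
#' @param path Output TSV for the matrix.
#' @param metadata_path Output TSV for the metadata.
#' @return `es`, invisibly.
#' @export
write_expression <- function(es, path, metadata_path) {
  stopifnot(inherits(es, "expression_set"))
  df <- as_tibble(es$values, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(es$metadata, metadata_path, progress = FALSE)
  invisible(es)
}

#' Collapse microarray probes to genes
#'
#' For genes measured by several probes, keeps the probe with the highest
#' mean expression; probes absent from the mapping are dropped. The mapping
#' of kept probes is attached as attribute `"collapse_map"`.
#'
#' @param es An [expression_set()] whose rows are probe ids.
#' @param mapping Data frame with columns `probe`, `gene` (or a named
#'   character vector probe -> gene).
#' @return An `expression_set` with one row per gene.
#' @export
collapse_probes <- function(es, mapping) {
  stopifnot(inherits(es, "expression_set"))
  if (is.character(mapping) && !is.null(names(mapping))) {
    mapping <- tibble(probe = names(mapping), gene = unname(mapping))
  }
  mapping <- as_tibble(mapping)
  if (!all(c("probe", "gene") %in% names(mapping)) || nrow(mapping) == 0) {
    abort("`mapping` must be non-empty with columns `probe` and `gene`.")
  }
  mapping <- dplyr::distinct(mapping, .data$probe, .data$gene) |>
    dplyr::filter(.data$probe %in% rownames(es$values))
  if (nrow(mapping) == 0) abort("Mapping covers no probes in the matrix.")
  means <- rowMeans(es$values)
  chosen <- mapping |>
    dplyr::mutate(mean_expr = means[.data$probe]) |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$mean_expr), .data$probe,
                   .by_group = TRUE) |>
    dplyr::summarise(probe = .data$probe[1],
                     n_probes = dplyr::n(),
                     mean_expr = .data$mean_expr[1]) |>
    dplyr::arrange(.data$gene)
  out <- es$values[chosen$probe, , drop = FALSE]
  rownames(out) <- chosen$gene
  res <- expression_set(out, es$metadata)
  attr(res, "collapse_map") <- chosen
  res
}

#' Remove outlier samples by mean inter-sample correlation
#'
#' A sample is removed when its mean Pearson correlation to all other
#' samples falls below the group mean minus `sd_mult` standard deviations
#' of that statistic; removal is iterated until stable. This emulates the
#' quality-control removal of grossly atypical arrays.
#'
#' @param es An [expression_set()] with at least 4 samples.
#' @param sd_mult Number of standard deviations below the mean that marks
#'   an outlier (default 3).
#' @param max_removed_frac Abort if more than this fraction of samples
#'   would be removed (default 0.2; such data are likely corrupt).
#' @return The filtered `expression_set`, with attribute `"qc_removed"`
#'   listing the removed sample ids (possibly empty).
#' @export
qc_filter_samples <- function(es, sd_mult = 3, max_removed_frac = 0.2) {
  stopifnot(inherits(es, "expression_set"))
  if (ncol(es$values) < 4) abort("QC needs at least 4 samples.")
  n0 <- ncol(es$values)
  removed <- character(0)
  vals <- es$values
  repeat {
    cc <- suppressWarnings(cor(vals))
    cc[is.na(cc)] <- 0
    diag(cc) <- NA
    mean_r <- colMeans(cc, na.rm = TRUE)
    cut <- mean(mean_r) - sd_mult * sd(mean_r)
    out <- names(mean_r)[mean_r < cut]
    if (length(out) == 0) break
    removed <- c(removed, out)
    if (length(removed) > max_removed_frac * n0) {
      abort(sprintf(
        "QC would remove %d of %d samples (> %.0f%%); data likely corrupt.",
        length(removed), n0, 100 * max_removed_frac))
    }
    vals <- vals[, setdiff(colnames(vals), out), drop = FALSE]
    if (ncol(vals) < 4) break
  }
  res <- expression_set(vals,
                        es$metadata[es$metadata$sample_id %in% colnames(vals), ])
  attr(res, "qc_removed") <- removed
  if (length(removed)) {
    inform(paste0("QC removed sample(s): ", paste(removed, collapse = ", ")))
  }
  res
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file (gzip accepted).
#' @return A named list of character vectors of class `gene_set_collection`
#'   with attribute `source` (the file path).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("Empty GMT file.")
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("Malformed GMT line %d: need name, description, >=1 gene.",
                    i))
    }
    nms[i] <- parts[1]
    sets[[i]] <- unique(parts[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    abort(paste0("Duplicated set name(s): ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  names(sets) <- nms
  structure(sets, class = "gene_set_collection", source = path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a co-expression edge table
#'
#' Three tab-separated columns: gene_a, gene_b, score. Confidence scores on
#' the integer 0-1000 scale (as in STRING flat files) are detected (any
#' score > 1) and divided by 1000 so that stored scores are in [0, 1].
#' Self-edges are dropped; duplicate unordered pairs keep the maximum
#' score.
#'
#' @param path Edge TSV (gzip accepted). A header line is tolerated.
#' @return A tibble with columns `gene_a`, `gene_b`, `score` (gene_a <
#'   gene_b, one row per unordered pair).
#' @export
read_edges <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("Empty edge file.")
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  start <- 1L
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) {
    start <- 2L  # header line
  }
  if (start > length(lines)) abort("Edge file has a header but no data.")
  rows <- lapply(seq(start, length(lines)), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("Malformed edge line %d: need gene_a, gene_b, score.", i))
    }
    sc <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(sc)) {
      abort(sprintf("Non-numeric score '%s' at edge line %d.", parts[3], i))
    }
    tibble(gene_a = parts[1], gene_b = parts[2], score = sc)
  })
  edges <- dplyr::bind_rows(rows)
  normalize_edges(edges)
}

# canonical form: [0,1] scores, no self-edges, one row per unordered pair
normalize_edges <- function(edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  if (any(edges$score < 0)) abort("Edge scores must be non-negative.")
  if (any(edges$score > 1)) edges$score <- edges$score / 1000
  if (any(edges$score > 1)) {
    abort("Edge scores exceed 1 even after 0-1000 scale normalization.")
  }
  edges |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::mutate(a = pmin(.data$gene_a, .data$gene_b),
                  b = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::rename(gene_a = "a", gene_b = "b") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Read a one-gene-per-line list
#'
#' @param path Text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return Character vector of unique gene symbols, in file order.
#' @export
read_gene_list <- function(path) {
  genes <- readr::read_lines(path, progress = FALSE)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  if (length(genes) == 0) abort("Empty gene list.")
  unique(genes)
}
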
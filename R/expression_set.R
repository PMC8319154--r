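#' Expression set: a genes x samples matrix plus sample metadata
#'
#' The basic container used throughout the package: a numeric matrix of
#' log2-scale expression values (genes in rows, samples in columns) tied to
#' a metadata tibble with one row per sample. All downstream operations
#' (correlation patterns, cluster expansion, t-statistics, deviation scores)
#' consume this container and return tibbles.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param metadata Data frame with columns `sample_id`, `diagnosis`
#'   (`"case"`/`"control"`), `region`, `dataset`; one row per sample.
#'
#' @return An object of class `expression_set` with elements `values`
#'   (matrix) and `metadata` (tibble, aligned to the matrix columns).
#' @export
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' md <- data.frame(sample_id = paste0("S", 1:4),
#'   diagnosis = c("case", "case", "control", "control"),
#'   region = "HPC", dataset = "toy")
#' es <- expression_set(m, md)
#' es
expression_set <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (anyNA(values)) abort("`values` must not contain missing values.")
  if (anyDuplicated(rownames(values))) {
    abort(paste0("Duplicated gene ids: ",
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    abort(paste0("Duplicated sample ids: ",
                 paste(unique(colnames(values)[duplicated(colnames(values))]),
                       collapse = ", ")))
  }
  metadata <- as_tibble(metadata)
  required <- c("sample_id", "diagnosis", "region", "dataset")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort("Metadata sample ids must be unique.")
  }
  bad_dx <- setdiff(unique(metadata$diagnosis), c("case", "control"))
  if (length(bad_dx)) {
    abort(paste0("`diagnosis` must be 'case' or 'control'; found: ",
                 paste(bad_dx, collapse = ", ")))
  }
  not_in_matrix <- setdiff(metadata$sample_id, colnames(values))
  if (length(not_in_matrix)) {
    abort(paste0("Metadata samples absent from the matrix: ",
                 paste(not_in_matrix, collapse = ", ")))
  }
  not_in_meta <- setdiff(colnames(values), metadata$sample_id)
  if (length(not_in_meta)) {
    abort(paste0("Matrix samples absent from the metadata: ",
                 paste(not_in_meta, collapse = ", ")))
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ]
  structure(list(values = values, metadata = metadata),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  n_case <- sum(x$metadata$diagnosis == "case")
  n_ctrl <- sum(x$metadata$diagnosis == "control")
  cat(sprintf(
    "<expression_set> %d genes x %d samples (%d case / %d control)\n",
    nrow(x$values), ncol(x$values), n_case, n_ctrl))
  cat("regions:", paste(unique(x$metadata$region), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Subset an expression set to a sample group
#'
#' @param es An [expression_set()].
#' @param group `"case"`, `"control"` or `"all"`.
#' @param region Optional region label; `NULL` keeps all regions.
#' @return An `expression_set` restricted to the selected samples.
#' @export
filter_samples <- function(es, group = c("all", "case", "control"),
                           region = NULL) {
  stopifnot(inherits(es, "expression_set"))
  group <- match.arg(group)
  keep <- rep(TRUE, ncol(es$values))
  if (group != "all") keep <- keep & es$metadata$diagnosis == group
  if (!is.null(region)) keep <- keep & es$metadata$region %in% region
  if (!any(keep)) abort("No samples match the requested group/region.")
  expression_set(es$values[, keep, drop = FALSE], es$metadata[keep, ])
}

#' Turn an expression set into a long tibble
#'
#' @param x An [expression_set()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `expression`, and
#'   the sample metadata columns.
#' @method tidy expression_set
#' @export
tidy.expression_set <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "expression")
  dplyr::left_join(long, x$metadata, by = "sample_id")
}

# group sample ids, with a minimum-count check
group_samples <- function(es, group, region = NULL, min_n = 1) {
  md <- es$metadata
  keep <- if (group == "all") rep(TRUE, nrow(md)) else md$diagnosis == group
  if (!is.null(region)) keep <- keep & md$region %in% region
  ids <- md$sample_id[keep]
  if (length(ids) < min_n) {
    abort(sprintf("Need at least %d '%s' samples%s; found %d.",
                  min_n, group,
                  if (is.null(region)) "" else paste0(" in region ", region),
                  length(ids)))
  }
  ids
}
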
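test_that("a toy expression file parses to the right shape and values", {
  dir <- withr::local_tempdir()
  expr <- file.path(dir, "e.tsv")
  meta <- file.path(dir, "m.tsv")
  writeLines(c("gene\tS1\tS2\tS3\tS4",
               "G1\t1.5\t2\t3\t4",
               "G2\t5\t6\t7\t8",
               "G3\t9\t10\t11\t12"), expr)
  writeLines(c("sample_id\tdiagnosis\tregion\tdataset",
               "S1\tcase\tHPC\td1", "S2\tcase\tHPC\td1",
               "S3\tcontrol\tHPC\td1", "S4\tcontrol\tHPC\td1"), meta)
  es <- read_expression(expr, meta, log2_transform = "no")
  expect_identical(dim(es), c(3L, 4L))
  expect_identical(rownames(es$values), c("G1", "G2", "G3"))
  expect_equal(es$values["G1", "S1"], 1.5)
  expect_identical(es$metadata$sample_id, colnames(es$values))
})

test_that("parse errors name the offending sample or cell", {
  dir <- withr::local_tempdir()
  expr <- file.path(dir, "e.tsv")
  meta <- file.path(dir, "m.tsv")
  writeLines(c("sample_id\tdiagnosis\tregion\tdataset",
               "S1\tcase\tHPC\td1", "S2\tcontrol\tHPC\td1",
               "S3\tcase\tHPC\td1", "S4\tcontrol\tHPC\td1"), meta)
  writeLines(c("gene\tS1\tS2\tS1\tS4", "G1\t1\t2\t3\t4"), expr)
  expect_error(read_expression(expr, meta), "S1")
  writeLines(c("gene\tS1\tS2\tS3\tS4", "G1\t1\toops\t3\t4"), expr)
  expect_error(read_expression(expr, meta), "oops")
  # matrix/metadata sample mismatch is a hard error either way
  writeLines(c("gene\tS1\tS2\tS3\tS9", "G1\t1\t2\t3\t4"), expr)
  expect_error(read_expression(expr, meta), "absent")
})

test_that("write/read round-trip preserves values and ordering", {
  es <- toy_matrix(n_genes = 20, seed = 3)
  paths <- write_toy_files(es)
  back <- read_expression(paths$expression, paths$metadata,
                          log2_transform = "no")
  expect_identical(rownames(back$values), rownames(es$values))
  expect_identical(colnames(back$values), colnames(es$values))
  expect_equal(back$values, es$values, tolerance = 1e-6)
})

test_that("auto log2 transform trips on linear-scale data only", {
  es <- toy_matrix(seed = 4)
  lin <- es
  lin$values <- 2^lin$values  # linear intensities, max >> 50
  paths <- write_toy_files(lin)
  expect_message(back <- read_expression(paths$expression, paths$metadata),
                 "log2")
  expect_lt(max(back$values), 50)
  paths2 <- write_toy_files(es)
  back2 <- read_expression(paths2$expression, paths2$metadata)
  expect_equal(back2$values, es$values, tolerance = 1e-6)
})

test_that("collapse_probes keeps the max-mean probe and drops unmapped", {
  m <- rbind(p1 = c(5, 5, 5, 5), p2 = c(7, 7, 7, 7), p3 = c(1, 1, 1, 1),
             p4 = c(2, 2, 2, 2))
  colnames(m) <- paste0("S", 1:4)
  md <- tibble::tibble(sample_id = colnames(m),
                       diagnosis = c("case", "case", "control", "control"),
                       region = "R", dataset = "d")
  es <- expression_set(m, md)
  mapping <- tibble::tibble(probe = c("p1", "p2", "p3"),
                            gene = c("A", "A", "B"))
  out <- collapse_probes(es, mapping)
  expect_identical(sort(rownames(out$values)), c("A", "B"))
  expect_equal(unname(out$values["A", ]), rep(7, 4))  # mean-7 probe wins
  expect_false("p4" %in% rownames(out$values))       # unmapped dropped
  # identity mapping, one probe per gene -> output equals input
  idmap <- tibble::tibble(probe = rownames(m), gene = rownames(m))
  out2 <- collapse_probes(es, idmap)
  expect_equal(out2$values[rownames(m), ], m)
  expect_error(collapse_probes(es, tibble::tibble(probe = character(),
                                                  gene = character())),
               "non-empty")
})

test_that("collapse_probes maps many probes onto the distinct gene count", {
  set.seed(5)
  n_probe <- 100
  m <- matrix(rnorm(n_probe * 4, 8), n_probe, 4,
              dimnames = list(sprintf("p%03d", 1:n_probe), paste0("S", 1:4)))
  md <- tibble::tibble(sample_id = paste0("S", 1:4),
                       diagnosis = c("case", "case", "control", "control"),
                       region = "R", dataset = "d")
  es <- expression_set(m, md)
  genes <- sprintf("G%02d", 1:60)
  mapping <- tibble::tibble(probe = rownames(m),
                            gene = sample(genes, n_probe, replace = TRUE))
  # make sure all 60 genes are hit
  mapping$gene[1:60] <- genes
  out <- collapse_probes(es, mapping)
  expect_identical(nrow(out$values), 60L)
  # kept probe's mean is >= mean of any discarded probe of the same gene
  means <- rowMeans(m)
  cmap <- attr(out, "collapse_map")
  for (g in cmap$gene) {
    probes_g <- mapping$probe[mapping$gene == g]
    kept <- cmap$probe[cmap$gene == g]
    expect_equal(means[kept], max(means[probes_g]), ignore_attr = TRUE)
  }
})

test_that("qc removes a planted noise sample, keeps homogeneous ones, and is idempotent", {
  set.seed(7)
  base <- rnorm(300, 8)
  vals <- sapply(1:18, function(i) base + rnorm(300, sd = 0.05))
  vals <- cbind(vals, rnorm(300, 8))  # independent-noise sample
  dimnames(vals) <- list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:19))
  md <- tibble::tibble(sample_id = colnames(vals),
                       diagnosis = c(rep("case", 10), rep("control", 9)),
                       region = "R", dataset = "d")
  es <- expression_set(vals, md)
  out <- suppressMessages(qc_filter_samples(es))
  expect_identical(attr(out, "qc_removed"), "S19")
  expect_identical(ncol(out$values), 18L)
  # idempotent: second pass removes nothing
  out2 <- qc_filter_samples(out)
  expect_length(attr(out2, "qc_removed"), 0)
  # homogeneous data: nothing removed
  hom <- toy_matrix(n_genes = 100, seed = 8)
  expect_length(attr(qc_filter_samples(hom), "qc_removed"), 0)
})

test_that("qc mirrors the one-of-17 case-sample removal and caps gross removal", {
  set.seed(9)
  base <- rnorm(500, 8)
  vals <- sapply(1:16, function(i) base + rnorm(500, sd = 0.1))
  vals <- cbind(vals, rnorm(500, 8))
  dimnames(vals) <- list(sprintf("G%03d", 1:500), sprintf("S%02d", 1:17))
  md <- tibble::tibble(sample_id = colnames(vals), diagnosis = "case",
                       region = "HPC", dataset = "d")
  md$diagnosis <- "case"
  es <- expression_set(vals, md)
  out <- suppressMessages(qc_filter_samples(es))
  expect_identical(ncol(out$values), 16L)
  # >20% removal aborts
  set.seed(10)
  bad <- matrix(rnorm(100 * 10, 8), 100, 10,
                dimnames = list(sprintf("G%03d", 1:100),
                                sprintf("S%02d", 1:10)))
  sh <- rnorm(100, 8)
  for (i in 1:6) bad[, i] <- sh + rnorm(100, sd = 0.01)
  md2 <- tibble::tibble(sample_id = colnames(bad), diagnosis = "case",
                        region = "R", dataset = "d")
  expect_error(suppressMessages(
    qc_filter_samples(expression_set(bad, md2), sd_mult = 0.5)),
    "corrupt")
})

test_that("GMT parsing follows the format and flags malformed lines", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "s.gmt")
  writeLines(c("pw1\tdesc\tA\tB\tC", "pw2\tdesc\tB\tD"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$pw1, c("A", "B", "C"))
  expect_identical(names(sets), c("pw1", "pw2"))
  writeLines(c("pw1\tdesc\tA", "broken_line"), gmt)
  expect_error(read_gmt(gmt), "line 2")
  # round-trip through write_gmt
  writeLines(c("pw1\tdesc\tA\tB\tC"), gmt)
  sets <- read_gmt(gmt)
  out <- file.path(dir, "o.gmt")
  write_gmt(sets, out)
  expect_identical(read_gmt(out)$pw1, c("A", "B", "C"))
})

test_that("edge tables are normalized, deduplicated and self-edge free", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "e.tsv")
  writeLines(c("A\tB\t850", "C\tD\t1000", "D\tC\t200", "E\tE\t900"), f)
  ed <- read_edges(f)
  expect_equal(ed$score[ed$gene_a == "A"], 0.85)  # per-mille auto-detected
  expect_identical(nrow(ed[ed$gene_a == "C", ]), 1L)
  expect_equal(ed$score[ed$gene_a == "C"], 1.0)   # max kept on dedup
  expect_false(any(ed$gene_a == ed$gene_b))
  # fractional dialect kept as-is; duplicate keeps max
  writeLines(c("A\tB\t0.2", "B\tA\t0.4"), f)
  ed2 <- read_edges(f)
  expect_equal(ed2$score, 0.4)
  writeLines(c("A\tB"), f)
  expect_error(read_edges(f), "line 1")
})
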
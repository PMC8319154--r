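# small in-code fixtures shared across test files

toy_matrix <- function(n_genes = 6, n_case = 5, n_ctrl = 5, seed = 1,
                       region = "HPC") {
  set.seed(seed)
  n <- n_case + n_ctrl
  m <- matrix(rnorm(n_genes * n, mean = 8), n_genes, n,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n))))
  md <- tibble::tibble(
    sample_id = colnames(m),
    diagnosis = c(rep("case", n_case), rep("control", n_ctrl)),
    region = region, dataset = "toy")
  expression_set(m, md)
}

write_toy_files <- function(es, dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
  paths <- list(expression = file.path(dir, "expr.tsv"),
                metadata = file.path(dir, "meta.tsv"))
  write_expression(es, paths$expression, paths$metadata)
  paths
}

# seeds a list of k cluster genes + n_extra independent listed genes
listed_genes <- function(truth, n_extra = 16, seed = 1) {
  set.seed(seed)
  c(truth$cluster, sample(truth$background, n_extra))
}

# brute-force upper-tail hypergeometric by subset enumeration
enum_hyper_p <- function(k, K, n, N) {
  first <- seq_len(K)  # which items are "in list 1" is exchangeable
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% first))
  mean(hits >= k)
}

# exact sign-test tail by enumeration of the binomial distribution
enum_binom_tail <- function(m, n) {
  sum(choose(n, m:n)) / 2^n
}
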
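scores_from_d <- function(d) tibble::tibble(gene = paste0("g", seq_along(d)),
                                            deviation = d)

test_that("deviation scores reproduce hand arithmetic", {
  # controls {1,2,3}, cases {4,4}: Mc=2, Sc=1, Mp=4, d=2
  m <- matrix(c(4, 4, 1, 2, 3,
                8, 8, 8, 8, 8), 2, 5, byrow = TRUE,
              dimnames = list(c("GA", "GB"), paste0("S", 1:5)))
  md <- tibble::tibble(sample_id = paste0("S", 1:5),
                       diagnosis = c("case", "case", rep("control", 3)),
                       region = "R", dataset = "d")
  es <- expression_set(m, md)
  expect_error(deviation_scores(es, "GA"), "case")  # needs >= 3 cases
  m2 <- cbind(m, S6 = c(4, 8))
  md2 <- dplyr::bind_rows(md, tibble::tibble(sample_id = "S6",
                                             diagnosis = "case",
                                             region = "R", dataset = "d"))
  es2 <- expression_set(m2, md2)
  sc <- suppressWarnings(deviation_scores(es2, c("GA", "GB")))
  expect_equal(sc$m_control[sc$gene == "GA"], 2)
  expect_equal(sc$s_control[sc$gene == "GA"], 1)
  expect_equal(sc$m_case[sc$gene == "GA"], 4)
  expect_equal(sc$deviation[sc$gene == "GA"], 2)
  # constant gene: Sc = 0 -> excluded with warning, not an error
  expect_warning(sc2 <- deviation_scores(es2, c("GA", "GB")), "zero control")
  expect_false("GB" %in% sc2$gene)
  expect_error(deviation_scores(es2, "MISSING"), "MISSING")
})

test_that("Mp equal to Mc gives deviation zero", {
  es <- toy_matrix(n_genes = 3, n_case = 4, n_ctrl = 4, seed = 2)
  es$values[1, ] <- c(1, 2, 3, 4, 4, 3, 2, 1)  # same mean both groups
  sc <- deviation_scores(es, rownames(es$values)[1])
  expect_equal(sc$deviation, 0)
})

test_that("mean deviation recovers the planted shift", {
  cfg <- synthetic_config(n_genes = 500, n_case = 200, n_ctrl = 200,
                          effect_size = 0.5, seed = 7)
  sim <- simulate_expression(cfg)
  sc <- deviation_scores(sim$expression, sim$truth$pathway)
  expect_lt(abs(mean(sc$deviation) - 0.5), 0.1)
})

test_that("negating the data negates d and flips the tendency direction", {
  cfg <- synthetic_config(n_genes = 200, seed = 8)
  sim <- simulate_expression(cfg)
  sc <- deviation_scores(sim$expression, sim$truth$pathway)
  es_neg <- sim$expression
  es_neg$values <- -es_neg$values
  sc_neg <- deviation_scores(es_neg, sim$truth$pathway)
  expect_equal(sc_neg$deviation, -sc$deviation)
  t1 <- tendency_test(sc); t2 <- tendency_test(sc_neg)
  expect_equal(t1$p_one_sided, t2$p_one_sided)
  expect_false(t1$direction == t2$direction)
})

test_that("network keeps only scored, connected genes above the strict threshold", {
  sc <- tibble::tibble(gene = c("A", "B", "C"),
                       m_control = 0, s_control = 1, m_case = 0,
                       deviation = c(0.5, -0.2, 1))
  edges <- tibble::tibble(gene_a = c("A", "A", "Z"),
                          gene_b = c("B", "C", "A"),
                          score = c(0.5, 0.1, 0.9))
  net <- build_network(sc, edges)
  # (A,C) at exactly 0.1 excluded; Z unscored; C left isolated -> dropped
  expect_setequal(net$nodes$gene, c("A", "B"))
  expect_identical(nrow(net$edges), 1L)
  expect_equal(igraph::V(net$graph)$deviation,
               sc$deviation[match(net$nodes$gene, sc$gene)])
  # empty result is a warning, not an error
  expect_warning(net0 <- build_network(sc, edges, min_score = 0.95),
                 "empty")
  expect_identical(nrow(net0$nodes), 0L)
})

test_that("network construction ignores edge record order and orientation", {
  sc <- tibble::tibble(gene = c("A", "B", "C"), deviation = c(1, 2, 3))
  e1 <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"),
                       score = c(0.5, 0.6))
  e2 <- tibble::tibble(gene_a = c("C", "B"), gene_b = c("B", "A"),
                       score = c(0.6, 0.5))
  n1 <- build_network(sc, e1)
  n2 <- build_network(sc, e2)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("a dense within-pathway edge pattern yields one dominant component", {
  ok <- vapply(1:20, function(i) {
    cfg <- synthetic_config(n_genes = 300, pathway_genes = 15, seed = i)
    sim <- simulate_expression(cfg)
    ed <- simulate_edges(sim$truth, p_within = 0.8, p_background = 0.02,
                         seed = i)
    sc <- suppressWarnings(
      deviation_scores(sim$expression, sim$truth$pathway))
    net <- build_network(sc, ed)
    comp <- igraph::components(net$graph)
    max(comp$csize) >= 0.9 * length(sim$truth$pathway)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("tendency test matches exact binomial tails and enumeration", {
  # 15 of 18 positive: tail = (C(18,15)+C(18,16)+C(18,17)+C(18,18))/2^18
  tt <- tendency_test(scores_from_d(c(rep(1, 15), rep(-1, 3))))
  expect_equal(tt$p_one_sided, 988 / 262144)
  expect_equal(tt$p_one_sided, 0.00377, tolerance = 1e-3)
  expect_identical(tt$direction, "up")
  # 9 of 18: p = P(X >= 9) ~ 0.593, ties resolve to up
  tt2 <- tendency_test(scores_from_d(c(rep(1, 9), rep(-1, 9))))
  expect_equal(tt2$p_one_sided, enum_binom_tail(9, 18))
  expect_equal(tt2$p_one_sided, 0.593, tolerance = 1e-3)
  expect_identical(tt2$direction, "up")
  # full sign-vector enumeration for small n
  for (n in c(5, 8, 11)) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (m in ceiling(n / 2):n) {
      p_enum <- mean(apply(signs, 1, function(s) max(sum(s > 0),
                                                     sum(s < 0))) >= m)
      # enumeration counts both directions; halve for the one-sided tail
      d <- c(rep(1, m), rep(-1, n - m))
      tt_nm <- tendency_test(scores_from_d(d), min_nonzero = 5)
      expect_equal(tt_nm$p_one_sided, enum_binom_tail(m, n))
      if (m > n / 2) expect_equal(p_enum, 2 * enum_binom_tail(m, n))
    }
  }
  # choose()-sum oracle for the 13..20 range
  for (n in 13:20) {
    m <- n - 3
    tt_n <- tendency_test(scores_from_d(c(rep(1, m), rep(-1, n - m))))
    expect_equal(tt_n$p_one_sided, enum_binom_tail(m, n), tolerance = 1e-12)
  }
  # zeros excluded; degenerate inputs error
  tt3 <- tendency_test(scores_from_d(c(rep(1, 6), rep(0, 4), rep(-1, 1))))
  expect_identical(tt3$n_pos + tt3$n_neg, 7L)
  expect_error(tendency_test(scores_from_d(rep(0, 8))), "zero")
  expect_error(tendency_test(scores_from_d(c(1, -1, 1))), "at least 5")
})

test_that("graphml/tsv export round-trips the network", {
  sc <- tibble::tibble(gene = c("A", "B"), deviation = c(0.3, -0.4))
  edges <- tibble::tibble(gene_a = "A", gene_b = "B", score = 0.7)
  net <- build_network(sc, edges)
  g <- withr::local_tempfile(fileext = ".graphml")
  t <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, g, t)
  back <- igraph::read_graph(g, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("A", "B"))
  expect_equal(sort(igraph::V(back)$deviation), c(-0.4, 0.3))
  expect_equal(igraph::E(back)$score, 0.7)
  expect_identical(nrow(readr::read_tsv(t, show_col_types = FALSE)), 1L)
})
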
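# coexpand

Integrating GWAS-derived gene lists with case/control expression data via
co-expression: correlation-pattern significance, cluster expansion,
enrichment, cross-dataset comparability, and pathway-level differential
expression.

## The problem

GWAS of polygenic disorders (the motivating application is major
depressive disorder, with post-mortem brain microarray cohorts of roughly
15–20 cases and 18–50 controls per region) yield a few dozen candidate
genes, each of small effect — too few and too uncertain for reliable
pathway enrichment, and individually never significant in differential
expression. `coexpand` is for analysts who want to move from such a list
to pathway-level statements, with every step testable and seeded:

1. **Correlation pattern.** Within one diagnosis group, count gene pairs
   whose Pearson correlation is significant (per-pair p from
   t = r·√((n−2)/(1−r²)); default level 5%). Significance of the pattern
   is the empirical probability that a random same-size gene group shows
   at least as many such pairs (B = 1000 draws).
2. **Cluster + expansion.** Find the coherent sub-cluster on a seriated
   correlation matrix, compute its per-sample average profile
   (eigengene-like), and extend to `M` genes (e.g. 800) by ranking all
   genes on correlation with the profile.
3. **Enrichment (ORA).** Upper-tail hypergeometric test of the expanded
   list against GMT gene sets, BH correction, score = −log₂(p_adj),
   tiers high/medium/low at 1e-4 and 0.05.
4. **Comparability.** Two datasets/regions are comparable when the
   Pearson correlation ρ of their per-gene case-vs-control t-statistics
   over shared genes has ρ > 0.1 and p < 0.001.
5. **Pathway-level differential expression.** Per-gene deviation
   d = (Mp − Mc)/Sc (case mean − control mean, in control-SD units),
   displayed on a co-expression network (edge score > 0.1), with an exact
   binomial sign test for a coordinated up/down tendency:
   p = P(X ≥ max(n₊, n₋)), X ~ Bin(n₊+n₋, ½).

A synthetic-data module generates datasets with this exact structure
(planted latent-factor cluster and pool, planted shifted pathway, known
truth) for calibration, power and recovery testing.

## Worked example

```r
library(coexpand)
set.seed(1)
dir <- tempfile("demo_")
cfg <- synthetic_config(n_genes = 2000, seed = 42)   # 16 case / 18 control
paths <- simulate_dataset(cfg, dir)                  # TSV + GMT + edges + truth
truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
writeLines(c(truth$cluster,
             sample(setdiff(sprintf("G%05d", 1:2000),
                            unlist(truth[c("cluster", "pool", "pathway")])), 16)),
           file.path(dir, "gwas.txt"))               # 23-gene "GWAS" list
res <- run_all(list(
  expression = paths$expression, metadata = paths$metadata,
  gene_list = file.path(dir, "gwas.txt"), gene_sets = paths$gene_sets,
  edges = paths$edges, out_dir = file.path(dir, "run"),
  B = 1000, M = 800, seed = 7, pathway_set = "planted_pathway"))

glance(res$corr_pattern)
#> # A tibble: 1 × 9
#>   observed_count     B threshold_mode threshold_value empirical_p ...
#> 1             32  1000 alpha                     0.05           0

res$cluster
#> <gene_cluster> 7 genes, mean pairwise r = 0.783
#>   G01252, G00634, G01177, G00321, G00561, G01098, G01170

res$expansion
#> <expanded_gene_list> 800 genes (seed 7 + 793 added), min r = 0.095

glance(res$pathway_de$tendency)
#> # A tibble: 1 × 5
#>   n_pos n_neg direction p_one_sided p_two_sided
#> 1    18     0 up         0.00000381  0.00000763
```

Reading: none of the 1000 random 23-gene groups matched the 32
significantly correlated pairs of the planted list (empirical p = 0, i.e.
p < 1/B); the detector recovered exactly the 7 planted cluster genes
(mean pairwise r 0.783); expansion to 800 genes added 793; and all 18
genes of the planted pathway deviate upward from controls, an exact sign
test p of 3.8 × 10⁻⁶. All stage outputs (JSON/TSV/GraphML) plus a
manifest land in `out_dir`, byte-identical across reruns with the same
seed.

Real data enter through `read_expression()` (genes × samples TSV plus a
sample metadata TSV with `sample_id`, `diagnosis`, `region`, `dataset`),
`collapse_probes()`, `qc_filter_samples()`, `read_gmt()` and
`read_edges()` (STRING-style tables; per-mille integer scores are
normalized to [0, 1] automatically).

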
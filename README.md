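# coenrich

Co-expression clustering and gene-set enrichment for drug repositioning.

Differential expression alone says *which* genes move in a disease, but not
which of them move *together*. Genes that are both differentially expressed
and tightly co-expressed are more likely to act as a coordinated programme —
a pathway being switched on, a cell-cycle burst, an immune module. `coenrich`
clusters disease-signature genes into co-expression groups and asks, group by
group, which pathways they enrich and which drug-perturbation signatures they
invert. Because drugs and pathways are enriched against the *same* clusters,
a repositioning candidate comes annotated with a putative mode of action: the
pathways enriched in the cluster it acts on. The package is aimed at
transcriptomics analysts doing pathway-level disease characterisation and
signature-reversal drug repositioning from bulk or single-cell DE gene lists.

## The method

1. **Co-expression clustering.** The DE-gene expression matrix (genes x
   samples, z-scored rows) is partitioned by any of ten clustering methods —
   hierarchical, agnes, diana, k-means, fanny, SOM, model-based (Gaussian
   mixture), SOTA, PAM, CLARA — under seven distance metrics (Euclidean,
   uncentred Pearson, absolute Pearson, centred correlation, absolute
   correlation, Spearman, biweight midcorrelation). Methods that do not
   support a metric fall back deterministically (`resolve_metric()`); grids
   over methods and cluster counts run serially or in parallel with identical
   results.

2. **Hypergeometric enrichment.** For a gene list of size *n* and a gene set
   with *m* members in a background universe of *N* genes, the enrichment
   p-value is the upper tail

   P(X ≥ k) = Σ_{x=k}^{min(m,n)} C(m,x) C(N−m, n−x) / C(N,n),

   where *k* is the observed overlap. P-values are Benjamini–Hochberg
   corrected per gene-list column and reported as the enrichment score
   −log2(FDR). Every cluster is tested, plus the "up", "down" and "all"
   DE-gene lists.

3. **Directional drug repositioning.** Drug-perturbation signatures are pairs
   of gene sets (top-100 up, bottom-100 down per treatment instance). Under
   the signature-reversal hypothesis, up-regulated clusters are tested
   against drugs' *down* sets and vice versa (`orientation = "inverse"`).
   Multi-instance drugs are merged above a score threshold
   (default −log2 0.05) by compound, cell line and/or concentration.

4. **Interaction connectivity.** For each cluster, the observed number of
   protein-protein interaction edges among its genes is compared with the
   degree-preserving expectation Σ_{i<j} min(1, d_i d_j / 2M), with a Poisson
   upper-tail p-value — a check that co-expressed clusters are also
   physically interacting modules.

A seeded synthetic-data generator (`synthetic_spec()`, `make_expression()`,
`make_genesets()`, `make_drug_signatures()`, `make_network()`) plants known
co-expression clusters, aligned pathway sets, inverse drug signatures and a
modular interaction network, so the whole pipeline is testable offline.

## Worked example

```r
library(coenrich)

spec <- synthetic_spec(seed = 1)          # 4 planted clusters x 30 genes
sim  <- make_expression(spec)
de   <- filter_de(sim$de_stats)           # FDR < 0.05 & |logFC| > 1
profile <- sim$profile
profile$matrix     <- profile$matrix[de$gene, ]
profile$regulation <- profile$regulation[de$gene]

assignment <- coex_cluster(profile, "pam", k = 4, metric = "correlation", seed = 1)
glance(assignment)
#>   method k_requested k_found metric_requested metric_used  seed n_genes
#> 1 pam              4       4 correlation      correlation     1     120

lists <- gene_lists(assignment, profile)  # clusters 1..4 + up/down/all
et    <- enrich(lists, make_genesets(spec, sim$truth))
glance(et)
#>   list  n_sets n_significant best_set   best_score
#> 1 1         24             1 PLANTED_C1      35.0
#> 2 2         24             1 PLANTED_C2      35.0
#> 3 3         24             1 PLANTED_C3      35.0
#> 4 4         24             1 PLANTED_C4      35.0
#> ...
```

Each planted pathway set is the single significant set of its own cluster,
with score −log2(FDR) ≈ 35 (FDR ≈ 3e−11); the 20 random decoy sets stay
below the −log2(0.05) ≈ 4.32 significance line. Repositioning against the
simulated drug-signature library under inverse orientation, then merging
instances by compound:

```r
drugs  <- make_drug_signatures(spec, sim$truth)
merged <- merge_instances(reposition(lists, drugs$collection), by = "compound")
merged[merged$list == "1", ]
#>   group_key compound direction list  score n_instances n_instances_total
#> 1 hitdrug1  hitdrug1 down      1      43.8           3                 3
#> 2 hitdrug3  hitdrug3 down      1      NA             0                 2
```

The drug planted to invert cluster 1 scores 43.8 with all 3 instances
passing; the drug targeting cluster 3 does not pass in this column — drugs
act on their own cluster. Connectivity of the planted network modules:

```r
net <- make_network(spec, sim$truth)
connectivity_summary(net, lists)
#>   list_label genes_in_list nodes_mapped observed expected ratio  p_value
#> 1 1                     30           30      133     31.7  4.19  7.6e-41
#> ...
#> 7 all                  120          120      594    582.   1.02  0.32
```

Within-cluster interactions run ~4x above the degree-preserving expectation
(the modular signal), while the pooled DE list is indistinguishable from the
null (ratio 1.02) — exactly why enrichment is done per cluster rather than on
the whole signature.

The same pipeline is scriptable from a shell via `inst/cli/coenrich`
(subcommands `simulate`, `cluster`, `enrich`, `reposition`, `ppi`,
`report`), which writes TSV results, run-metadata JSON and PNG/SVG heatmaps.

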
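---
title: "Methods: co-expression clustering, enrichment and repositioning in coenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression clustering, enrichment and repositioning in coenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coenrich)
```

# The model

`coenrich` operates on the expression matrix of differentially expressed
genes — genes that pass hard thresholds on an upstream DE analysis
(`filter_de()`: FDR < 0.05 and |logFC| > 1 by default, both strict, applied
to a user-supplied statistics table; the DE model fit itself is upstream and
out of scope). The working hypothesis is that DE genes which are also
co-expressed across samples form coordinated transcriptional programmes, and
that enrichment of *those groups* — rather than of the pooled signature — is
what links disease biology to drug action.

The pipeline is: (1) partition the DE genes into co-expression clusters;
(2) test every cluster (and the "up", "down" and "all" DE lists) for
enrichment against pathway gene sets and against directional
drug-perturbation signatures; (3) summarise intra-cluster protein-interaction
connectivity as a structural sanity check on the clusters.

## Clustering

Rows are z-scored before clustering (`scale_rows()`); per-gene standardisation
is what makes Euclidean geometry on rows behave like correlation and puts
genes with different dynamic ranges on one scale. Zero-variance genes are an
error rather than silently dropped.

Seven distance metrics are available (`distance_matrix()`): Euclidean;
uncentred Pearson (the cosine of the raw rows — kept distinct from the
centred "correlation" metric, following the convention of the clustering
ecosystem this interface mirrors); absolute Pearson; centred correlation;
absolute correlation; Spearman (Pearson on within-row average ranks); and the
biweight midcorrelation with tuning constant 9 (median/MAD-based bisquare
weights, written in-house since no installed package provides it; rows whose
MAD is zero fall back to sd/9 weights, the conventional degenerate-case
treatment).

Ten clustering methods are exposed (`coex_cluster()`), delegating to the
standard engines where they exist: `stats::hclust` (average linkage) and
`cluster::agnes`/`diana`/`fanny`/`pam`/`clara`, `stats::kmeans`,
`class::batchSOM` on a k-by-1 grid, and `mclust::Mclust` restricted to the
diagonal-covariance family. The self-organising tree algorithm (SOTA) is
implemented in-house (no installed engine): two daughter cells grow from the
data centroid; each training cycle presents every profile in fixed order and
relocates the winning cell toward it (learning rate 0.01), with weaker
updates to the winner's sister (0.001) and mother (0.005); cycles cap at
1000 epochs or a 1e-6 relative change in total resource; the leaf with the
highest resource (mean member-centroid dissimilarity) is split until k
leaves exist. These rates and caps are fixed defaults of this
implementation, chosen to match common SOTA practice.

Not every method supports every metric; `resolve_metric()` applies the
fallback rules deterministically (k-means: biwt to correlation; CLARA:
everything except Euclidean/Manhattan to Euclidean; SOTA: everything except
correlation/Euclidean to correlation; SOM: always Euclidean; model-based:
its own likelihood). Every substitution is recorded in the assignment's
notes and in the CLI run metadata.

Design choices where the interface left the design open:

* **Linkage** for hierarchical/agnes is average (UPGMA) — robust for
  correlation distances — with the engine's default behaviour otherwise;
  agnes is kept as a separate method for interface fidelity even though it
  shares the agglomerative-average contract with `hclust`.
* **Coordinate-based methods** (k-means, SOM, model, CLARA) receive the
  z-scored rows. Under correlation-family requests this is an approximation:
  squared Euclidean distance on standardised rows is proportional to
  centred-correlation distance, which is exactly why rows are standardised
  first.
* **k-means** runs Lloyd iterations with 10 restarts; if Lloyd strands an
  empty cluster the cell retries with MacQueen (which reassigns
  immediately), and the event is recorded.
* **Seeding**: one user seed; each (method, k) grid cell derives its own
  stream by hashing the triple, so `cluster_grid()` is bit-identical whether
  run serially or on forked workers, and a failing cell is recorded without
  aborting the grid.
* **Ties** in nearest-medoid/centroid assignment break toward the lowest
  cluster index; labels are always relabelled to contiguous 1..k_found
  (preserving numeric order), and `k_found < k` (empty SOM units, degenerate
  mixture components) is recorded, not an error. `k_found < 2` is an error.
* There is deliberately **no automatic selection** of method or k.
  `selection_report()` quantifies the guiding principles — a coherent set
  should concentrate in as few clusters as possible, and the cluster
  attaining its maximum score should be small — but the choice is the
  analyst's.

## Enrichment

For a gene list with *n* genes in the background and a set with *m*, the
p-value is the hypergeometric upper tail of the overlap *k*, accumulated in
log space (`lchoose` + log-sum-exp) so deep tails are stable
(`hypergeom_upper_tail()`); the implementation is cross-checked in the tests
against exhaustive subset enumeration at small N and against `phyper` across
the full small-universe grid.

* **Background universe N** defaults to the collection universe (the union of
  all set members); supply the platform's measured genes when available — N
  materially changes p-values, and the choice is echoed into run metadata.
* **BH scope**: correction runs per gene-list column across all sets of one
  collection, because each column is one hypothesis family ("which sets
  match this cluster"); whether to correct jointly across clusters is an
  open convention, and per-column was chosen and documented.
* **Scores** are −log2(FDR), floored at the smallest positive normalised
  double before the log so they stay finite; capped cells carry a flag.
* **Absent vs zero**: a list with no background overlap yields absent (NA)
  cells; absent cells render as 0 in heatmaps and count as 0 in mean/max
  rank aggregation — the literal reading of ranking by "mean of the clusters
  and all DE genes".
* **Ranking** (`rank_sets()`): mean/max aggregate the cluster columns plus
  the "all" column; single-column modes sort that column; ties break
  lexicographically by set name for determinism.
* **Cluster direction** is the majority regulation of member genes; exact
  ties give "mixed", which is tested against both signature directions.
* The significance threshold used for merging is computed as −log2(0.05),
  never hard-coded as a decimal.

## Drug signatures and repositioning

A treatment instance's signature is built from its ranked profile
(`build_signature_sets()`): top-100 up, bottom-100 down (the down set stored
most-down-first). A fixed count, rather than a statistical threshold, keeps
signatures comparable across instances. The cut is applied per supplied
ranked profile; aggregating replicate profiles before cutting is left to the
caller. Set names encode compound, cell type, concentration (verbatim, units
embedded), instance and direction as
`compound@cell@conc@inst#up|down` — unambiguous, greppable, and lossless
through GMT round-trips. Compounds compare case-insensitively when grouping.

`reposition()` defaults to inverse orientation — disease-up clusters vs drug
down sets — the signature-reversal hypothesis; `"same"` exists to flag drugs
that might induce the phenotype (e.g. as a side effect), `"both"` disables
filtering. `merge_instances()` aggregates instances above the threshold by
mean (default) or max; both are exposed because published merged views do
not pin the aggregator down.

## Interaction connectivity

For a gene list, `observed_edges()` counts network edges with both endpoints
in the list; genes missing from the network are excluded from both sides of
the comparison. The expectation under a degree-preserving null is the
Chung–Lu form Σ min(1, d_i d_j / 2M), and the p-value is the Poisson upper
tail at that mean (`connectivity_pvalue()`; observed 0 gives p = 1). These
are deliberate approximations of the summary statistics interaction
databases report: the exact null (uniform simple graphs with fixed degrees)
has no closed form, so the tests validate the expectation against
stub-matching rewires (10,000 draws on a 50-node graph, agreement within 3
Monte-Carlo standard errors) rather than against any external service.
Ratios are stored at full precision; the display value rounds half-up to two
decimals, matching the convention of published interaction tables. Edge
confidences/weights are not modelled — the edge list is treated as already
thresholded.

# The synthetic generator

`synthetic_spec()` defaults describe the study conditions all recovery
properties are evaluated under: 4 planted clusters of 30 genes plus 40
background genes, 20 case + 20 control samples, latent-factor loading
rho = 0.9, noise sd 0.3, case-control effect 2.0 with alternating cluster
sign, pathway-set coverage 0.7 with 20 size-matched decoys, and seed 1.

A planted gene follows
`x = s_c * effect * 1[case] + sqrt(rho) * z_cj + sqrt(1 - rho) * e_gj`,
with one latent signal z per cluster and sample. The latent-factor
construction (rather than sampling a full covariance matrix) costs O(genes)
memory and pins the within/between correlation structure exactly. Background
genes are unit-variance noise. The DE table is *computed from the generated
matrix* (Welch t statistics, BH-adjusted) rather than sampled independently,
so `filter_de()` is exercised honestly; at the default effect size planted
genes pass the thresholds and background genes fail them. Note one
consequence of the planted disease effect: clusters sharing a sign are
correlated *across* groups through the case-control shift, so between-cluster
independence holds net of group means — the generator emulates co-expression
conditional on disease status.

Drug signatures live on a simulated platform pool (default 2000 genes)
because real perturbation signatures are drawn from a whole-array universe
much larger than the DE list; hit drugs get 2–3 instances whose down sets
contain 60% of the target cluster padded to exactly 100 genes, inert drugs
get random 100-gene sets. The interaction network is a stochastic block
model (within-cluster edge probability 0.3, background 0.01).

What the generator does **not** emulate: probe effects, batch structure,
heavy-tailed microarray noise, correlated decoy sets, partially overlapping
pathways, or any real disease signal. Passing the recovery properties
therefore shows the pipeline is correct and well-calibrated under clean
modular signal — not that any particular real dataset will cluster well.

# Calibration and test design

Two properties anchor the statistics. First, enrichment p-values of random
decoy sets are null-calibrated: raw hypergeometric p-values are discrete and
therefore super-uniform (their CDF sits on or below the diagonal), so the
tests check super-uniformity of the raw values directly and exact
uniformity of the randomized PIT `P(X > k) + U * P(X = k)` — the standard
way to test calibration of a discrete p-value. Second, the degree-preserving
expectation matches the mean of stub-matching rewires within Monte-Carlo
error. Recovery properties run at 50 seeded replicates of the default
generator conditions (120 DE genes by 40 samples per replicate); these sizes
keep the full suite in the low tens of seconds while giving the rate
estimates ~7% standard error.

# Limitations

* Method/k selection is manual by design; the diagnostics are advisory.
* The Poisson tail overstates significance slightly when the expected count
  is large relative to the list size (variance of the true null is below
  Poisson); ratios near 1 should not be over-read.
* The uncentred-"pearson" vs centred-"correlation" naming follows the
  ecosystem convention the interface mirrors; users expecting "pearson" to
  mean centred correlation should request `correlation`.
* Upstream normalisation, DE modelling and probe-to-symbol mapping are out
  of scope: the package starts from a DE statistics table and an expression
  matrix on a shared identifier space.
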
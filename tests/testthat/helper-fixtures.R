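# Shared fixture builders; everything is generated in code under fixed seeds.

# Two planted co-expression blobs (n_per genes each) via a shared latent
# factor: within-module correlation ~ rho, between ~ 0.
two_blob_profile <- function(n_per = 10, n_samples = 8, rho = 0.95, seed = 42) {
  set.seed(seed)
  z1 <- rnorm(n_samples); z2 <- rnorm(n_samples)
  rows <- rbind(
    t(sapply(seq_len(n_per), function(i) sqrt(rho) * z1 + sqrt(1 - rho) * rnorm(n_samples))),
    t(sapply(seq_len(n_per), function(i) sqrt(rho) * z2 + sqrt(1 - rho) * rnorm(n_samples)))
  )
  rownames(rows) <- sprintf("G%03d", seq_len(2 * n_per))
  colnames(rows) <- sprintf("S%d", seq_len(n_samples))
  expression_profile(
    rows,
    sample_group = rep(c("case", "control"), length.out = n_samples),
    regulation = rep(c("up", "down"), each = n_per)
  )
}

# Random gene-set collection for round-trip properties.
random_collection <- function(n_sets = 10, seed = 1) {
  set.seed(seed)
  pool <- sprintf("GENE%03d", 1:200)
  gene_set_collection(
    name = sprintf("SET_%02d", seq_len(n_sets)),
    description = sample(c("", "some description", "x y z"), n_sets, replace = TRUE),
    genes = lapply(seq_len(n_sets), function(i) sample(pool, sample(3:30, 1)))
  )
}

# Map each truth cluster to the assignment label holding most of its genes.
match_clusters <- function(labels, truth_clusters) {
  tab <- table(labels, truth_clusters)
  vapply(colnames(tab), function(tc) rownames(tab)[which.max(tab[, tc])],
         character(1))
}

# One full recovery replicate on synthetic defaults: PAM at k = n_clusters,
# pathway enrichment, inverse drug repositioning. Returns per-seed checks.
recovery_replicate <- function(seed) {
  spec <- synthetic_spec(seed = seed)
  sim <- make_expression(spec)
  de <- filter_de(sim$de_stats)
  prof <- sim$profile
  prof$matrix <- prof$matrix[de$gene, , drop = FALSE]
  prof$regulation <- prof$regulation[de$gene]
  asg <- coex_cluster(prof, "pam", spec$n_clusters, "correlation", seed = seed)
  truth <- sim$truth$cluster[match(names(asg$labels), sim$truth$gene)]
  ari <- mclust::adjustedRandIndex(asg$labels, truth)

  lists <- gene_lists(asg, prof)
  sets <- make_genesets(spec, sim$truth)
  et <- enrich(lists, sets)
  cl_of_truth <- match_clusters(asg$labels, truth)
  pathway_ok <- all(vapply(seq_len(spec$n_clusters), function(c_idx) {
    cl <- cl_of_truth[[as.character(c_idx)]]
    ranked <- rank_sets(et, cl)
    top <- ranked$set[1L]
    fdr_top <- tidy(et) |>
      dplyr::filter(set == top, list == cl) |>
      dplyr::pull(fdr)
    top == sprintf("PLANTED_C%d", c_idx) && fdr_top < 0.05
  }, logical(1)))

  drugs <- make_drug_signatures(spec, sim$truth)
  rp <- reposition(lists, drugs$collection, orientation = "inverse")
  drug_ok <- all(vapply(seq_len(nrow(drugs$hits)), function(i) {
    cl <- cl_of_truth[[as.character(drugs$hits$target_cluster[i])]]
    ranked <- rank_sets(rp, cl)
    compounds <- parse_instance_name(ranked$set)$compound
    drugs$hits$compound[i] %in% utils::head(unique(compounds), 3L)
  }, logical(1)))

  list(ari = ari, pathway_ok = pathway_ok, drug_ok = drug_ok,
       pass = ari >= 0.9 && pathway_ok && drug_ok)
}

# Stub-matching (configuration-model) rewire: pair stubs uniformly at random
# and count stub-pairs joining two distinct members of `genes` (multiplicity
# included) -- the degree-preserving null that expected_edges() approximates.
stub_rewire_count <- function(degree, genes) {
  stubs <- rep(names(degree), degree)
  perm <- sample(stubs)
  a <- perm[seq(1, length(perm), by = 2)]
  b <- perm[seq(2, length(perm), by = 2)]
  sum(a %in% genes & b %in% genes & a != b)
}
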
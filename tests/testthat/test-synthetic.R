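test_that("make_expression is deterministic and plants the advertised structure", {
  spec <- synthetic_spec()
  a <- make_expression(spec)
  b <- make_expression(spec)
  expect_identical(a$profile$matrix, b$profile$matrix)
  expect_identical(a$de_stats, b$de_stats)

  n_planted <- spec$n_clusters * spec$genes_per_cluster
  expect_equal(nrow(a$profile$matrix),
               n_planted + spec$n_background_genes)
  expect_equal(ncol(a$profile$matrix), spec$n_case + spec$n_control)

  # planted genes pass the default DE filter; background genes fail it
  de <- filter_de(a$de_stats)
  planted <- a$truth$gene[!is.na(a$truth$cluster)]
  expect_setequal(de$gene, planted)

  # planted regulation follows the alternating cluster sign
  expect_true(all(de$regulation[match(a$truth$gene[a$truth$cluster %in% c(1, 3)],
                                      de$gene)] == "up", na.rm = TRUE))

  # within-cluster correlation high, between-cluster low
  m <- a$profile$matrix
  c1 <- a$truth$gene[!is.na(a$truth$cluster) & a$truth$cluster == 1]
  c2 <- a$truth$gene[!is.na(a$truth$cluster) & a$truth$cluster == 2]
  within <- cor(t(m[c1, ]))
  expect_gte(mean(within[upper.tri(within)]), 0.7)
  # between-cluster co-expression is assessed net of the case/control shift
  # (the planted disease effect correlates clusters across groups by design)
  grp <- a$profile$sample_group
  centred <- m
  for (g in unique(grp)) {
    centred[, grp == g] <- m[, grp == g] - rowMeans(m[, grp == g])
  }
  between <- cor(t(centred[c1, ]), t(centred[c2, ]))
  expect_lte(mean(abs(between)), 0.2)
})

test_that("noise_sd -> 0 drives within-cluster correlations toward 1", {
  spec <- synthetic_spec(noise_sd = 1e-6, seed = 2)
  sim <- make_expression(spec)
  m <- sim$profile$matrix
  c1 <- sim$truth$gene[!is.na(sim$truth$cluster) & sim$truth$cluster == 1]
  within <- cor(t(m[c1, ]))
  expect_gte(min(within[upper.tri(within)]), 0.999)
})

test_that("make_genesets covers planted clusters and matches decoy sizes", {
  spec <- synthetic_spec(seed = 3)
  sim <- make_expression(spec)
  sets <- make_genesets(spec, sim$truth)
  expect_equal(nrow(sets), spec$n_clusters + spec$n_decoy_sets)
  expect_true(all(lengths(sets$genes) == spec$genes_per_cluster))

  overlap_with <- function(set_genes, c_idx) {
    cl <- sim$truth$gene[!is.na(sim$truth$cluster) & sim$truth$cluster == c_idx]
    length(intersect(set_genes, cl))
  }
  for (c_idx in seq_len(spec$n_clusters)) {
    own <- overlap_with(sets$genes[[c_idx]], c_idx)
    others <- vapply(setdiff(seq_len(spec$n_clusters), c_idx),
                     function(o) overlap_with(sets$genes[[c_idx]], o),
                     numeric(1))
    expect_equal(own, round(spec$set_coverage * spec$genes_per_cluster))
    expect_true(all(own > others))
  }

  # full coverage includes the whole cluster
  full <- make_genesets(synthetic_spec(set_coverage = 1, seed = 3), sim$truth)
  cl1 <- sim$truth$gene[!is.na(sim$truth$cluster) & sim$truth$cluster == 1]
  expect_true(all(cl1 %in% full$genes[[1]]))
})

test_that("decoy-set overlaps with a planted cluster follow the hypergeometric null", {
  spec <- synthetic_spec(seed = 1)
  sim <- make_expression(spec)
  cl1 <- sim$truth$gene[!is.na(sim$truth$cluster) & sim$truth$cluster == 1]
  n_genes <- nrow(sim$truth)
  overlaps <- unlist(lapply(1:30, function(s) {
    sets <- make_genesets(synthetic_spec(seed = s), sim$truth)
    vapply(sets$genes[-(1:4)], function(g) length(intersect(g, cl1)), numeric(1))
  }))
  # compare empirical CDF with the hypergeometric CDF at every support point
  ks <- 0:30
  emp <- ecdf(overlaps)(ks)
  theo <- phyper(ks, length(cl1), n_genes - length(cl1), 30)
  expect_lt(max(abs(emp - theo)), 0.05)
})

test_that("drug signatures have exactly 100 members and hit their target cluster", {
  spec <- synthetic_spec(seed = 4)
  sim <- make_expression(spec)
  drugs <- make_drug_signatures(spec, sim$truth)
  expect_true(all(lengths(drugs$collection$genes) == 100L))
  meta <- parse_instance_name(drugs$collection$name)
  expect_true(all(meta$direction %in% c("up", "down")))

  for (i in seq_len(nrow(drugs$hits))) {
    cl_genes <- sim$truth$gene[!is.na(sim$truth$cluster) &
                                 sim$truth$cluster == drugs$hits$target_cluster[i]]
    down_sets <- drugs$collection$genes[
      meta$compound == drugs$hits$compound[i] & meta$direction == "down"]
    for (s in down_sets) {
      expect_gte(length(intersect(s, cl_genes)), 0.6 * length(cl_genes))
    }
    up_sets <- drugs$collection$genes[
      meta$compound == drugs$hits$compound[i] & meta$direction == "up"]
    expect_gte(length(down_sets), 2)
    expect_lte(length(down_sets), 3)
    for (s in up_sets) {
      expect_equal(length(intersect(s, cl_genes)), 0)
    }
  }
})

test_that("make_network is a seeded stochastic block model", {
  spec <- synthetic_spec(seed = 1)
  sim <- make_expression(spec)
  net <- make_network(spec, sim$truth)
  expect_identical(net$edges, make_network(spec, sim$truth)$edges)

  # within-cluster edge count close to p_within * C(g, 2)
  cl1 <- sim$truth$gene[!is.na(sim$truth$cluster) & sim$truth$cluster == 1]
  n_pairs <- choose(length(cl1), 2)
  obs <- observed_edges(net, cl1)
  expect_lt(abs(obs - 0.3 * n_pairs), 3 * sqrt(n_pairs * 0.3 * 0.7))

  # zero probabilities give no network at all
  expect_null(make_network(spec, sim$truth, p_within = 0, p_between = 0))
})

test_that("simulate_bundle writes a complete, reloadable fixture directory", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(seed = 6)
  paths <- simulate_bundle(spec, dir)
  expect_true(all(file.exists(unlist(paths))))
  col <- read_gmt(paths$pathways)
  expect_equal(nrow(col), spec$n_clusters + spec$n_decoy_sets)
  net <- read_edge_list(paths$network)
  expect_gt(net$M, 0)
  de <- readr::read_tsv(paths$de_stats, show_col_types = FALSE)
  expect_named(de, c("gene", "logFC", "FDR"))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$spec$seed, 6)
})
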
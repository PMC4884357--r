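test_that("hypergeometric upper tail matches enumeration and the hand-worked case", {
  # whole support: k = 0 is exactly 1
  expect_identical(hypergeom_upper_tail(0, 4, 5, 10), 1)
  # (C(4,3)C(6,2) + C(4,4)C(6,1)) / C(10,5) = 66/252
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)

  # exhaustive subset enumeration for small universes
  for (N in c(6, 8, 10)) {
    for (m in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        draws <- utils::combn(N, n)
        annotated <- colSums(draws <= m)  # genes 1..m are the annotated ones
        for (k in 0:min(m, n)) {
          expect_equal(
            hypergeom_upper_tail(k, m, n, N),
            mean(annotated >= k),
            tolerance = 1e-12,
            label = sprintf("k=%d m=%d n=%d N=%d", k, m, n, N)
          )
        }
      }
    }
  }
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "k <= min")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "m <= N")
})

test_that("hypergeometric tail is monotone non-increasing in k", {
  for (params in list(c(20, 30, 100), c(5, 5, 12), c(50, 40, 200))) {
    m <- params[1]; n <- params[2]; N <- params[3]
    ks <- 0:min(m, n)
    p <- hypergeom_upper_tail(ks, m, n, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)

  step_up_oracle <- function(p) {
    M <- length(p)
    ord <- order(p)
    q <- p[ord] * M / seq_len(M)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(ord)]
  }
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, step_up_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # invariant under permutation of input order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("enrich finds planted sets, marks absent cells, handles the degenerate case", {
  spec <- synthetic_spec(seed = 8)
  sim <- make_expression(spec)
  de <- filter_de(sim$de_stats)
  prof <- sim$profile
  prof$matrix <- prof$matrix[de$gene, , drop = FALSE]
  prof$regulation <- prof$regulation[de$gene]
  asg <- coex_cluster(prof, "pam", 4, seed = 8)
  lists <- gene_lists(asg, prof)
  sets <- make_genesets(spec, sim$truth)
  et <- enrich(lists, sets)

  truth <- sim$truth$cluster[match(names(asg$labels), sim$truth$gene)]
  cl_of <- match_clusters(asg$labels, truth)
  for (c_idx in 1:4) {
    cl <- cl_of[[as.character(c_idx)]]
    ranked <- rank_sets(et, cl)
    expect_equal(ranked$set[1], sprintf("PLANTED_C%d", c_idx))
    cell <- tidy(et) |> dplyr::filter(set == ranked$set[1], list == cl)
    expect_lt(cell$fdr, 0.05)
  }
  # fdr >= p_raw everywhere, so significant-set counts are nested
  cells <- tidy(et) |> dplyr::filter(!is.na(p_raw))
  expect_true(all(cells$fdr >= cells$p_raw - 1e-15))
  expect_true(all(cells$k <= pmin(cells$n, cells$m)))

  # a list disjoint from the background gives absent cells, not zeros
  ghost <- tibble::tibble(label = "ghost", genes = list(c("NOPE1", "NOPE2")),
                          n_genes = 2L, direction = "mixed")
  et2 <- enrich(ghost, sets)
  expect_true(all(is.na(tidy(et2)$score)))

  # query list = gene set = background: k = n = m = N, p = 1
  one <- gene_set_collection("ONLY", genes = list(c("A", "B", "C")))
  et3 <- enrich(tibble::tibble(label = "q", genes = list(c("A", "B", "C")),
                               n_genes = 3L, direction = "mixed"), one)
  expect_equal(tidy(et3)$p_raw, 1)
})

test_that("enrichment scores are invariant to cluster relabelling and gene order", {
  spec <- synthetic_spec(seed = 15)
  sim <- make_expression(spec)
  de <- filter_de(sim$de_stats)
  prof <- sim$profile
  prof$matrix <- prof$matrix[de$gene, , drop = FALSE]
  prof$regulation <- prof$regulation[de$gene]
  asg <- coex_cluster(prof, "pam", 4, seed = 15)
  lists <- gene_lists(asg, prof)
  sets <- make_genesets(spec, sim$truth)
  base_scores <- tidy(enrich(lists, sets))

  # permute cluster labels: scores follow the permutation, values unchanged
  perm <- c(2L, 3L, 4L, 1L)
  relabelled <- asg
  relabelled$labels <- setNames(perm[asg$labels], names(asg$labels))
  perm_scores <- tidy(enrich(gene_lists(relabelled, prof), sets))
  for (cl in 1:4) {
    a <- base_scores |> dplyr::filter(list == as.character(cl)) |>
      dplyr::arrange(set)
    b <- perm_scores |> dplyr::filter(list == as.character(perm[cl])) |>
      dplyr::arrange(set)
    expect_equal(a$score, b$score)
  }

  # shuffling gene order within lists changes nothing
  shuffled <- lists
  set.seed(1)
  shuffled$genes <- lapply(shuffled$genes, sample)
  expect_equal(tidy(enrich(shuffled, sets))$score, base_scores$score)
})

test_that("rank_sets matches a brute-force sort oracle in every mode", {
  set.seed(99)
  sets <- sprintf("SET%02d", 1:30)
  cols <- c(as.character(1:4), "up", "down", "all")
  long <- tidyr::expand_grid(set = sets, list = cols) |>
    dplyr::mutate(
      n = 10L, m = 5L, k = 2L, N = 100L, p_raw = runif(dplyr::n()),
      score = round(runif(dplyr::n(), 0, 12), 3), fdr = 2^-score,
      capped = FALSE
    )
  lists <- tibble::tibble(label = cols, genes = list("X"), n_genes = 1L,
                          direction = "mixed")
  et <- coenrich:::new_enrichment_tbl(long, lists, 100L)

  wide <- long |> dplyr::select(set, list, score) |>
    tidyr::pivot_wider(names_from = list, values_from = score)
  agg_cols <- c(as.character(1:4), "all")  # mean/max pool clusters + "all"
  for (mode in c("mean", "max", "all", "up", "down", "2")) {
    ranked <- rank_sets(et, mode)
    key <- switch(mode,
      mean = rowMeans(wide[agg_cols]),
      max = apply(wide[agg_cols], 1, max),
      wide[[mode]]
    )
    oracle <- wide$set[order(-key, wide$set)]
    expect_equal(ranked$set, oracle, label = paste("mode", mode))
  }
  expect_error(rank_sets(et, "9"), "no gene-list column")
  one_col <- coenrich:::new_enrichment_tbl(long |> dplyr::filter(list == "all"),
                                           lists[lists$label == "all", ], 100L)
  expect_equal(rank_sets(one_col, "mean")$set, rank_sets(one_col, "max")$set)
})

test_that("reposition filters directions by orientation", {
  spec <- synthetic_spec(seed = 23)
  sim <- make_expression(spec)
  de <- filter_de(sim$de_stats)
  prof <- sim$profile
  prof$matrix <- prof$matrix[de$gene, , drop = FALSE]
  prof$regulation <- prof$regulation[de$gene]
  asg <- coex_cluster(prof, "pam", 4, seed = 23)
  lists <- gene_lists(asg, prof)
  drugs <- make_drug_signatures(spec, sim$truth)

  inv <- tidy(reposition(lists, drugs$collection, orientation = "inverse"))
  dirs <- attr(lists, "names")  # quiet lint; direction map below
  list_dir <- setNames(lists$direction, lists$label)
  up_lists <- names(list_dir)[list_dir == "up"]
  down_lists <- names(list_dir)[list_dir == "down"]
  expect_true(all(inv$set_direction[inv$list %in% up_lists] == "down"))
  expect_true(all(inv$set_direction[inv$list %in% down_lists] == "up"))

  same <- tidy(reposition(lists, drugs$collection, orientation = "same"))
  expect_true(all(same$set_direction[same$list %in% up_lists] == "up"))

  both <- tidy(reposition(lists, drugs$collection, orientation = "both"))
  expect_gte(nrow(both), nrow(inv))
  expect_gte(nrow(both), nrow(same))
  key <- function(d) paste(d$set, d$list)
  expect_true(all(key(inv) %in% key(both)))
  expect_true(all(key(same) %in% key(both)))

  # collection without parseable directions is refused
  plain <- gene_set_collection("JUSTASET", genes = list(c("A", "B")))
  expect_error(reposition(lists, plain), "direction")
})

test_that("merge_instances aggregates passing instances and keeps counts", {
  lists <- tibble::tibble(label = "1", genes = list("X"), n_genes = 1L,
                          direction = "up")
  mk_row <- function(inst, score) {
    tibble::tibble(
      set = encode_instance_name("drugA", "MCF7", "1uM", inst, "down"),
      list = "1", n = 10L, m = 100L, k = 5L, N = 1000L,
      p_raw = 2^-score, fdr = 2^-score, score = score, capped = FALSE,
      compound = "drugA", cell_type = "MCF7", concentration = "1uM",
      instance = inst, set_direction = "down"
    )
  }
  long <- dplyr::bind_rows(mk_row("i1", 5), mk_row("i2", 6), mk_row("i3", 0))
  et <- coenrich:::new_enrichment_tbl(long, lists, 1000L)

  merged <- merge_instances(et, threshold = -log2(0.05), by = "compound",
                            aggregator = "mean")
  expect_equal(nrow(merged), 1)
  expect_equal(merged$score, 5.5)          # mean of the two passing scores
  expect_equal(merged$n_instances, 2L)
  expect_equal(merged$n_instances_total, 3L)

  max_all <- merge_instances(et, threshold = 0, aggregator = "max")
  expect_equal(max_all$score, 6)           # columnwise max when all pass

  # merging by every key field is the identity on scores
  ident <- merge_instances(et, threshold = 0,
                           by = c("compound", "cell_type", "concentration",
                                  "instance"))
  expect_equal(nrow(ident), 3)
  expect_setequal(ident$score, c(5, 6, 0))
  expect_true(all(ident$n_instances_total == 1L))

  # nothing passing leaves an empty result
  none <- merge_instances(et, threshold = 100)
  expect_equal(nrow(none), 0)
})
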
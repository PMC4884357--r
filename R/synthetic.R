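#' Specification for synthetic fixtures
#'
#' Parameters of the seeded generator that emulates the structure the
#' pipeline assumes: differentially expressed genes that co-express in
#' groups, pathway sets aligned with those groups, directional drug
#' signatures that invert them, and a modular interaction network.
#'
#' @param n_clusters number of planted co-expression clusters (default 4).
#' @param genes_per_cluster genes per planted cluster (default 30).
#' @param n_background_genes non-DE noise genes (default 40).
#' @param n_case,n_control samples per group (default 20 + 20).
#' @param within_correlation latent-factor loading rho in (0,1): planted
#'   genes share `sqrt(rho)` of a per-cluster latent signal (default 0.9).
#' @param noise_sd standard deviation of the per-gene noise term (default 0.3).
#' @param effect_size case-vs-control mean shift per planted cluster, applied
#'   with alternating sign so clusters alternate up-/down-regulated
#'   (default 2.0).
#' @param set_coverage fraction of a planted cluster included in its planted
#'   pathway set (default 0.7).
#' @param n_decoy_sets number of size-matched random decoy pathway sets
#'   (default 20).
#' @param n_platform_genes size of the simulated measurement platform's gene
#'   pool from which drug-signature padding and inert signatures are drawn
#'   (default 2000; real perturbation signatures live on a whole-array
#'   universe much larger than the DE-gene list).
#' @param n_inert_drugs number of no-signal drug compounds (default 4).
#' @param seed integer seed driving every draw (default 1).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 4L, genes_per_cluster = 30L,
                           n_background_genes = 40L, n_case = 20L,
                           n_control = 20L, within_correlation = 0.9,
                           noise_sd = 0.3, effect_size = 2.0,
                           set_coverage = 0.7, n_decoy_sets = 20L,
                           n_platform_genes = 2000L, n_inert_drugs = 4L,
                           seed = 1L) {
  spec <- list(
    n_clusters = as.integer(n_clusters),
    genes_per_cluster = as.integer(genes_per_cluster),
    n_background_genes = as.integer(n_background_genes),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    within_correlation = within_correlation, noise_sd = noise_sd,
    effect_size = effect_size, set_coverage = set_coverage,
    n_decoy_sets = as.integer(n_decoy_sets),
    n_platform_genes = as.integer(n_platform_genes),
    n_inert_drugs = as.integer(n_inert_drugs),
    seed = as.integer(seed)
  )
  with(spec, {
    assert_that(n_clusters >= 1 && genes_per_cluster >= 2 &&
                  n_background_genes >= 0 && n_case >= 2 && n_control >= 2 &&
                  n_decoy_sets >= 0 && n_inert_drugs >= 0,
                "all counts must be positive")
    assert_that(within_correlation > 0 && within_correlation < 1,
                "within_correlation must lie in (0, 1)")
    assert_that(noise_sd > 0, "noise_sd must be positive")
    assert_that(set_coverage > 0 && set_coverage <= 1,
                "set_coverage must lie in (0, 1]")
    assert_that(n_platform_genes >=
                  n_clusters * genes_per_cluster + n_background_genes + 200L,
                "platform pool must exceed the profile genes by at least 200")
  })
  structure(spec, class = "synthetic_spec")
}

planted_gene_ids <- function(spec) {
  unlist(lapply(seq_len(spec$n_clusters), function(c) {
    sprintf("CL%d_G%02d", c, seq_len(spec$genes_per_cluster))
  }))
}

platform_pool <- function(spec) {
  profile_genes <- c(planted_gene_ids(spec),
                     sprintf("BG_G%03d", seq_len(spec$n_background_genes)))
  extra <- sprintf("EXT_G%04d",
                   seq_len(spec$n_platform_genes - length(profile_genes)))
  c(profile_genes, extra)
}

#' Generate a synthetic expression profile with planted clusters
#'
#' Planted gene g of cluster c in sample j follows
#' `x = s_c * effect * 1[j is case] + sqrt(rho) * z_cj + sqrt(1 - rho) * e_gj`
#' with a latent signal `z_cj ~ N(0,1)` shared by the cluster in each sample,
#' independent noise `e_gj ~ N(0, noise_sd)`, and alternating cluster sign
#' `s_c` (odd clusters up-regulated in cases, even clusters down).
#' Background genes are pure unit-variance noise. The differential-expression
#' table is computed from the generated matrix itself (two-sample Welch t
#' statistics, BH-adjusted), so at the default effect size the planted genes
#' pass [filter_de()] thresholds and the background genes fail them.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `profile` (an [expression_profile()] over all generated
#'   genes), `truth` (tibble `gene, cluster, regulation_truth`; background
#'   genes have `cluster = NA`), and `de_stats` (tibble `gene, logFC, FDR`).
#' @export
make_expression <- function(spec) {
  set.seed(spec$seed)
  n_samples <- spec$n_case + spec$n_control
  sample_ids <- c(sprintf("CASE_%02d", seq_len(spec$n_case)),
                  sprintf("CTRL_%02d", seq_len(spec$n_control)))
  is_case <- rep(c(1, 0), c(spec$n_case, spec$n_control))
  rho <- spec$within_correlation

  planted <- planted_gene_ids(spec)
  bg <- sprintf("BG_G%03d", seq_len(spec$n_background_genes))
  genes <- c(planted, bg)
  m <- matrix(0, nrow = length(genes), ncol = n_samples,
              dimnames = list(genes, sample_ids))

  for (c_idx in seq_len(spec$n_clusters)) {
    s_c <- if (c_idx %% 2L == 1L) 1 else -1
    z <- rnorm(n_samples)
    rows <- (c_idx - 1L) * spec$genes_per_cluster + seq_len(spec$genes_per_cluster)
    for (r in rows) {
      eps <- rnorm(n_samples, sd = spec$noise_sd)
      m[r, ] <- s_c * spec$effect_size * is_case + sqrt(rho) * z +
        sqrt(1 - rho) * eps
    }
  }
  if (spec$n_background_genes > 0L) {
    m[bg, ] <- matrix(rnorm(spec$n_background_genes * n_samples),
                      nrow = spec$n_background_genes)
  }

  case_cols <- seq_len(spec$n_case)
  tt <- apply(m, 1L, function(row) {
    t <- t.test(row[case_cols], row[-case_cols])
    c(logFC = unname(diff(rev(t$estimate))), p = t$p.value)
  })
  de_stats <- tibble(gene = genes, logFC = tt["logFC", ],
                     FDR = bh_adjust(tt["p", ]))

  profile <- expression_profile(
    m,
    sample_group = setNames(rep(c("case", "control"),
                                c(spec$n_case, spec$n_control)), sample_ids),
    regulation = setNames(ifelse(de_stats$logFC > 0, "up", "down"), genes)
  )
  truth <- tibble(
    gene = genes,
    cluster = c(rep(seq_len(spec$n_clusters), each = spec$genes_per_cluster),
                rep(NA_integer_, spec$n_background_genes)),
    regulation_truth = c(rep(ifelse(seq_len(spec$n_clusters) %% 2L == 1L,
                                    "up", "down"),
                             each = spec$genes_per_cluster),
                         rep(NA_character_, spec$n_background_genes))
  )
  list(profile = profile, truth = truth, de_stats = de_stats)
}

#' Generate planted and decoy pathway sets
#'
#' One planted set per cluster: a `set_coverage` fraction of the cluster's
#' genes plus random off-cluster padding keeping the set at
#' `genes_per_cluster` members, so decoy sets of the same size are
#' comparable. Decoys are drawn uniformly from all generated genes.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `truth` tibble from [make_expression()].
#' @return A [gene_set_collection()] of planted + decoy sets.
#' @export
make_genesets <- function(spec, truth) {
  set.seed(derive_seed(spec$seed, "genesets", 0L))
  all_genes <- truth$gene
  n_in <- round(spec$set_coverage * spec$genes_per_cluster)
  size <- spec$genes_per_cluster
  planted <- lapply(seq_len(spec$n_clusters), function(c_idx) {
    cl_genes <- truth$gene[!is.na(truth$cluster) & truth$cluster == c_idx]
    inside <- sample(cl_genes, n_in)
    pad <- sample(setdiff(all_genes, cl_genes), size - n_in)
    c(inside, pad)
  })
  decoys <- lapply(seq_len(spec$n_decoy_sets), function(i) {
    sample(all_genes, size)
  })
  gene_set_collection(
    name = c(sprintf("PLANTED_C%d", seq_len(spec$n_clusters)),
             sprintf("DECOY_%02d", seq_len(spec$n_decoy_sets))),
    description = c(rep("planted pathway", spec$n_clusters),
                    rep("decoy pathway", spec$n_decoy_sets)),
    genes = c(planted, decoys)
  )
}

#' Generate directional drug-signature sets
#'
#' For each planted up-regulated cluster, a "hit" drug with 2-3 instances
#' whose down-regulated sets contain 60 percent of the cluster's genes,
#' padded to exactly 100 members with random platform genes from outside the
#' cluster; the paired up-regulated sets, and all sets of the inert drugs,
#' are random 100-gene draws from the platform pool. Set names encode
#' compound, cell type, concentration, instance and direction.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `truth` tibble from [make_expression()].
#' @return A list: `collection` (a [gene_set_collection()]) and `hits`
#'   (tibble `compound, target_cluster`).
#' @export
make_drug_signatures <- function(spec, truth) {
  set.seed(derive_seed(spec$seed, "drugs", 0L))
  pool <- platform_pool(spec)
  cells <- c("MCF7", "PC3", "HL60")
  up_clusters <- seq_len(spec$n_clusters)[seq_len(spec$n_clusters) %% 2L == 1L]

  names_ <- character(0); genes_ <- list(); hit_rows <- list()
  add_set <- function(nm, g) {
    names_ <<- c(names_, nm)
    genes_[[length(genes_) + 1L]] <<- g
  }
  for (idx in seq_along(up_clusters)) {
    c_idx <- up_clusters[idx]
    compound <- sprintf("hitdrug%d", c_idx)
    cl_genes <- truth$gene[!is.na(truth$cluster) & truth$cluster == c_idx]
    n_hit <- ceiling(0.6 * length(cl_genes))
    n_inst <- 2L + (idx %% 2L)  # alternate 3, 2 instances
    for (inst in seq_len(n_inst)) {
      core <- sample(cl_genes, n_hit)
      pad <- sample(setdiff(pool, cl_genes), 100L - n_hit)
      down_set <- c(core, pad)
      up_set <- sample(setdiff(pool, cl_genes), 100L)
      key <- list(cell = cells[(inst - 1L) %% length(cells) + 1L],
                  conc = "1e-06M", inst = sprintf("inst%02d", inst))
      add_set(encode_instance_name(compound, key$cell, key$conc, key$inst, "down"),
              down_set)
      add_set(encode_instance_name(compound, key$cell, key$conc, key$inst, "up"),
              up_set)
    }
    hit_rows[[idx]] <- tibble(compound = compound, target_cluster = c_idx)
  }
  for (i in seq_len(spec$n_inert_drugs)) {
    compound <- sprintf("inertdrug%d", i)
    for (inst in 1:2) {
      key <- list(cell = cells[(inst - 1L) %% length(cells) + 1L],
                  conc = "1e-05M", inst = sprintf("inst%02d", inst))
      add_set(encode_instance_name(compound, key$cell, key$conc, key$inst, "down"),
              sample(pool, 100L))
      add_set(encode_instance_name(compound, key$cell, key$conc, key$inst, "up"),
              sample(pool, 100L))
    }
  }
  list(
    collection = gene_set_collection(name = names_, description = "",
                                     genes = genes_),
    hits = bind_rows(hit_rows)
  )
}

#' Generate a modular interaction network
#'
#' Stochastic block model over the generated genes: pairs within the same
#' planted cluster are connected with probability `p_within`, all other pairs
#' with probability `p_between`.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `truth` tibble from [make_expression()].
#' @param p_within,p_between edge probabilities (defaults 0.3 and 0.01).
#' @return An [interaction_network()], or `NULL` if no edges were drawn.
#' @export
make_network <- function(spec, truth, p_within = 0.3, p_between = 0.01) {
  set.seed(derive_seed(spec$seed, "network", 0L))
  genes <- truth$gene
  cl <- truth$cluster
  n <- length(genes)
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    same <- !is.na(cl[i]) & !is.na(cl[j]) & cl[i] == cl[j]
    p <- ifelse(same, p_within, p_between)
    hit <- runif(length(j)) < p
    if (any(hit)) {
      from <- c(from, rep(genes[i], sum(hit)))
      to <- c(to, genes[j][hit])
    }
  }
  if (length(from) == 0L) return(NULL)
  interaction_network(tibble(from = from, to = to))
}

#' Write a full synthetic fixture bundle to disk
#'
#' Generates expression, annotation, DE statistics, pathway and drug GMTs,
#' the interaction edge list and a ground-truth JSON into `dir`, all driven
#' by `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_expression(spec)
  sets <- make_genesets(spec, sim$truth)
  drugs <- make_drug_signatures(spec, sim$truth)
  net <- make_network(spec, sim$truth)

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    de_stats = file.path(dir, "de_stats.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    drugs = file.path(dir, "drugs.gmt"),
    network = file.path(dir, "network.tsv"),
    truth = file.path(dir, "truth.json")
  )
  expr_tbl <- as.data.frame(sim$profile$matrix) |>
    tibble::rownames_to_column("gene")
  readr::write_tsv(expr_tbl, paths$expression)
  readr::write_tsv(tibble(sample_id = colnames(sim$profile$matrix),
                          group = unname(sim$profile$sample_group)),
                   paths$annotation)
  readr::write_tsv(sim$de_stats, paths$de_stats)
  write_gmt(sets, paths$pathways)
  write_gmt(drugs$collection, paths$drugs)
  if (!is.null(net)) readr::write_tsv(net$edges, paths$network,
                                      col_names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec),
         truth = sim$truth,
         hits = drugs$hits),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
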
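#' @importFrom mclust Mclust mclustBIC
NULL

#' Clustering methods registry
#'
#' The ten co-expression clustering methods exposed by the package:
#' hierarchical (agglomerative, average linkage), agnes, diana (divisive),
#' k-means, fanny (fuzzy), SOM (self-organising map on a k-by-1 grid),
#' model (Gaussian mixture, diagonal covariances), SOTA (self-organising
#' tree), PAM (k-medoids) and CLARA (subsampled PAM).
#'
#' @return Character vector of method names.
#' @export
coex_methods <- function() {
  c("hierarchical", "agnes", "diana", "kmeans", "fanny", "som", "model",
    "sota", "pam", "clara")
}

# Relabel an integer vector to contiguous 1..k_found, preserving the numeric
# order of the original labels (deterministic).
relabel_contiguous <- function(labels) {
  u <- sort(unique(labels))
  match(labels, u)
}

#' Cluster differentially expressed genes
#'
#' Partitions the genes of an expression profile into `k` co-expression
#' clusters with one of the ten methods in [coex_methods()]. Rows are
#' z-scored before clustering; the requested metric is passed through
#' [resolve_metric()] and any substitution is recorded in the result.
#' Coordinate-based methods (k-means, SOM, model, CLARA) operate on the
#' standardised rows, under which Euclidean geometry approximates correlation
#' distance.
#'
#' Methods may return fewer clusters than requested (empty SOM units,
#' degenerate mixture components); `k_found` records the realised count and
#' labels are always contiguous `1..k_found`.
#'
#' @param profile an [expression_profile()].
#' @param method one of [coex_methods()].
#' @param k requested number of clusters (`2 <= k <` number of genes).
#' @param metric requested distance metric, see [distance_matrix()].
#' @param seed integer seed; every stochastic method draws from a stream
#'   derived from `(seed, method, k)` so grid runs are schedule-independent.
#' @return A `cluster_assignment` object: named integer labels plus
#'   method/metric/seed metadata. Use [tidy()] for a `gene, cluster` tibble.
#' @export
coex_cluster <- function(profile, method, k, metric = "correlation", seed = 1L) {
  method <- match.arg(method, coex_methods())
  n <- nrow(profile$matrix)
  assert_that(k >= 2L && k < n, "k must satisfy 2 <= k < number of genes")
  metric_used <- resolve_metric(method, metric)
  notes <- character(0)
  if (!identical(metric_used, metric)) {
    notes <- paste0("metric fallback: ", metric, " -> ", metric_used)
  }

  profile <- scale_rows(profile)
  x <- profile$matrix
  cell_seed <- derive_seed(seed, method, k)
  set.seed(cell_seed)

  needs_dist <- method %in% c("hierarchical", "agnes", "diana", "fanny", "pam")
  d <- if (needs_dist || method == "sota") {
    if (method == "sota") NULL else distance_matrix(profile, metric_used)
  }

  labels <- switch(
    method,
    hierarchical = cutree(hclust(stats::as.dist(d), method = "average"), k = k),
    agnes = cutree(as.hclust(cluster::agnes(stats::as.dist(d), diss = TRUE,
                                            method = "average")), k = k),
    diana = cutree(as.hclust(cluster::diana(stats::as.dist(d), diss = TRUE)), k = k),
    kmeans = fit_kmeans(x, k),
    fanny = cluster::fanny(stats::as.dist(d), k = k, diss = TRUE, memb.exp = 2,
                           maxit = 2000)$clustering,
    som = fit_som(x, k),
    model = fit_model(x, k),
    sota = fit_sota(x, k, metric_used),
    pam = cluster::pam(stats::as.dist(d), k = k, cluster.only = TRUE),
    clara = cluster::clara(x, k = k, metric = metric_used, samples = 5,
                           sampsize = min(n, 40 + 2 * k), rngR = TRUE,
                           pamLike = TRUE)$clustering
  )

  labels <- relabel_contiguous(as.integer(labels))
  names(labels) <- rownames(x)
  k_found <- max(labels)
  if (k_found < 2L) abort("clustering collapsed to a single cluster (k_found < 2)")
  if (k_found < k) notes <- c(notes, paste0("k_found ", k_found, " < k ", k))

  structure(
    list(method = method, k_requested = as.integer(k), k_found = k_found,
         metric_requested = metric, metric_used = metric_used,
         labels = labels, seed = as.integer(seed), notes = notes),
    class = "cluster_assignment"
  )
}

fit_kmeans <- function(x, k) {
  # Lloyd iterations with >= 10 restarts; Lloyd can strand an empty cluster
  # on unlucky starts, in which case MacQueen (which reassigns immediately)
  # is retried with the same stream.
  res <- tryCatch(
    kmeans(x, centers = k, iter.max = 200, nstart = 10, algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(res)) {
    res <- kmeans(x, centers = k, iter.max = 200, nstart = 10,
                  algorithm = "MacQueen")
  }
  res$cluster
}

fit_som <- function(x, k) {
  grid <- class::somgrid(xdim = k, ydim = 1L, topo = "rectangular")
  som <- class::batchSOM(x, grid = grid, radii = c(2, 2, 1, 1, 0, 0))
  unit <- as.integer(class::knn1(som$codes, x, factor(seq_len(nrow(som$codes)))))
  unit  # empty units handled by contiguous relabelling downstream
}

fit_model <- function(x, k) {
  # Gaussian mixture, diagonal covariance family by default.
  fit <- Mclust(x, G = k,
                modelNames = c("EII", "VII", "EEI", "VEI", "EVI", "VVI"),
                verbose = FALSE)
  if (is.null(fit)) {
    fit <- Mclust(x, G = k, modelNames = "EII", verbose = FALSE)
  }
  if (is.null(fit)) abort("Gaussian-mixture fit failed to converge")
  fit$classification
}

# ---- SOTA: self-organising tree algorithm -----------------------------------
# Divisive binary-tree clustering: two daughter cells grow from the data
# centroid; each training cycle relocates winner cells (and, more weakly,
# their sister and mother) toward the presented profiles; the leaf with the
# highest resource (mean member-centroid dissimilarity) is split until k
# leaves exist. Dissimilarity is correlation (1 - r) or Euclidean.
sota_dissim <- function(x, centroid, metric) {
  if (metric == "euclidean") {
    sqrt(colSums((t(x) - centroid)^2))
  } else {
    1 - suppressWarnings(as.vector(cor(t(x), centroid)))
  }
}

fit_sota <- function(x, k, metric, lr_winner = 0.01, lr_mother = 0.005,
                     lr_sister = 0.001, max_epochs = 1000, tol = 1e-6) {
  n <- nrow(x)
  root <- colMeans(x)
  # node table: centroids in a list; parent/sister indices; leaves flagged
  centroids <- list(root,
                    root + rnorm(ncol(x), sd = 1e-3),
                    root + rnorm(ncol(x), sd = 1e-3))
  parent <- c(NA_integer_, 1L, 1L)
  sister <- c(NA_integer_, 3L, 2L)
  is_leaf <- c(FALSE, TRUE, TRUE)

  train_cycle <- function() {
    leaves <- which(is_leaf)
    last_res <- Inf
    for (epoch in seq_len(max_epochs)) {
      dmat <- vapply(leaves, function(i) sota_dissim(x, centroids[[i]], metric),
                     numeric(n))
      win <- leaves[max.col(-dmat, ties.method = "first")]
      for (g in seq_len(n)) {
        w <- win[g]
        centroids[[w]] <<- centroids[[w]] + lr_winner * (x[g, ] - centroids[[w]])
        s <- sister[w]
        if (!is.na(s) && is_leaf[s]) {
          centroids[[s]] <<- centroids[[s]] + lr_sister * (x[g, ] - centroids[[s]])
        }
        p <- parent[w]
        if (!is.na(p)) {
          centroids[[p]] <<- centroids[[p]] + lr_mother * (x[g, ] - centroids[[p]])
        }
      }
      res <- sum(dmat[cbind(seq_len(n), match(win, leaves))])
      if (is.finite(last_res) && abs(last_res - res) <= tol * max(1, last_res)) break
      last_res <- res
    }
    win
  }

  win <- train_cycle()
  while (sum(is_leaf) < k) {
    leaves <- which(is_leaf)
    resource <- vapply(leaves, function(i) {
      members <- which(win == i)
      if (length(members) == 0L) return(-Inf)
      mean(sota_dissim(x[members, , drop = FALSE], centroids[[i]], metric))
    }, numeric(1))
    split_at <- leaves[which.max(resource)]
    m <- length(centroids)
    centroids[[m + 1L]] <- centroids[[split_at]] + rnorm(ncol(x), sd = 1e-3)
    centroids[[m + 2L]] <- centroids[[split_at]] + rnorm(ncol(x), sd = 1e-3)
    parent <- c(parent, split_at, split_at)
    sister <- c(sister, m + 2L, m + 1L)
    is_leaf[split_at] <- FALSE
    is_leaf <- c(is_leaf, TRUE, TRUE)
    win <- train_cycle()
  }
  match(win, which(is_leaf))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", x$method, ", k = ", x$k_requested,
      " (found ", x$k_found, "), metric = ", x$metric_used, "\n", sep = "")
  print(table(cluster = x$labels))
  if (length(x$notes)) cat("  notes: ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Derive gene lists from a cluster assignment
#'
#' Builds the query lists for enrichment: one list per cluster (labelled
#' `"1"..k`), plus `"up"` (all DE genes with up regulation), `"down"`, and
#' `"all"` (every DE gene). Each cluster's direction is the majority
#' regulation of its members; exact ties give `"mixed"`.
#'
#' @param assignment a `cluster_assignment` from [coex_cluster()].
#' @param profile the [expression_profile()] that was clustered.
#' @return A tibble `label, genes (list), n_genes, direction`.
#' @export
gene_lists <- function(assignment, profile) {
  reg <- profile$regulation
  labs <- assignment$labels
  assert_that(all(names(labs) %in% names(reg)),
              "assignment genes not found in profile")
  cluster_rows <- lapply(seq_len(assignment$k_found), function(cl) {
    g <- names(labs)[labs == cl]
    r <- reg[g]
    dir <- if (sum(r == "up") > sum(r == "down")) "up"
           else if (sum(r == "down") > sum(r == "up")) "down" else "mixed"
    tibble(label = as.character(cl), genes = list(g), n_genes = length(g),
           direction = dir)
  })
  all_g <- names(reg)
  extra <- tibble(
    label = c("up", "down", "all"),
    genes = list(all_g[reg == "up"], all_g[reg == "down"], all_g),
    n_genes = c(sum(reg == "up"), sum(reg == "down"), length(all_g)),
    direction = c("up", "down", "mixed")
  )
  bind_rows(bind_rows(cluster_rows), extra)
}

#' Run a grid of clustering methods and cluster counts
#'
#' Clusters the profile once per (method, k) combination. Each cell draws its
#' random numbers from a stream derived from `(seed, method, k)`, so results
#' are bit-identical whether the grid is executed serially or concurrently. A
#' failing cell is recorded with its error message and does not abort the
#' grid.
#'
#' @param profile an [expression_profile()].
#' @param methods character vector of methods from [coex_methods()].
#' @param k_range integer vector of cluster counts (all >= 2).
#' @param metric requested distance metric.
#' @param seed integer seed.
#' @param parallel if `TRUE`, cells run concurrently via forked workers.
#' @param cores number of workers when `parallel` (default 2).
#' @return A `coex_grid` tibble: `method, k, assignment (list), ok, error`.
#' @export
cluster_grid <- function(profile, methods = coex_methods(), k_range = 2:20,
                         metric = "correlation", seed = 1L, parallel = FALSE,
                         cores = 2L) {
  assert_that(length(k_range) > 0L && all(k_range >= 2L),
              "k_range must be non-empty with all entries >= 2")
  methods <- vapply(methods, match.arg, character(1), choices = coex_methods())
  cells <- tidyr::expand_grid(method = unname(methods), k = as.integer(k_range))
  run_cell <- function(i) {
    tryCatch(
      list(ok = TRUE, error = NA_character_,
           assignment = coex_cluster(profile, cells$method[i], cells$k[i],
                                     metric = metric, seed = seed)),
      error = function(e) list(ok = FALSE, error = conditionMessage(e),
                               assignment = NULL)
    )
  }
  results <- if (parallel && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(cells)), run_cell, mc.cores = cores,
                       mc.set.seed = FALSE)
  } else {
    lapply(seq_len(nrow(cells)), run_cell)
  }
  out <- cells |>
    mutate(
      assignment = lapply(results, `[[`, "assignment"),
      ok = vapply(results, `[[`, logical(1), "ok"),
      error = vapply(results, `[[`, character(1), "error")
    )
  class(out) <- c("coex_grid", class(out))
  out
}

#' Per-cell diagnostics for method and k selection
#'
#' There is no automatic way to pick the clustering method and cluster count;
#' the guiding principles are that a coherent gene set should concentrate in
#' as few clusters as possible (ideally one) and that the cluster attaining a
#' set's maximum score should be small, to maximise the enrichment score.
#' This report quantifies both for every grid cell; it is advisory only.
#'
#' @param grid a `coex_grid` from [cluster_grid()].
#' @param enrichments a list of [enrich()] tables, one per grid row (failed
#'   cells may be `NULL`).
#' @param fdr_max significance threshold on the FDR (default 0.05).
#' @return A tibble with one row per grid cell: `method, k, n_significant`
#'   (sets with FDR < `fdr_max` in at least one cluster column),
#'   `mean_dispersion`/`max_dispersion` (number of cluster columns in which a
#'   significant set is significant), `min_cluster_size_at_max` (size of the
#'   smallest cluster attaining a significant set's maximum score), and a
#'   `per_set` list-column of the underlying per-set counts.
#' @export
selection_report <- function(grid, enrichments, fdr_max = 0.05) {
  assert_that(length(enrichments) == nrow(grid),
              "need one enrichment table (or NULL) per grid cell")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    et <- enrichments[[i]]
    base <- tibble(method = grid$method[i], k = grid$k[i])
    if (is.null(et) || !isTRUE(grid$ok[i])) {
      return(base |> mutate(n_significant = NA_integer_,
                            mean_dispersion = NA_real_,
                            max_dispersion = NA_integer_,
                            min_cluster_size_at_max = NA_integer_,
                            per_set = list(NULL)))
    }
    cl_cols <- et |> filter(!.data$list %in% c("up", "down", "all"))
    sizes <- cl_cols |> distinct(.data$list, .data$n) |>
      (\(d) setNames(d$n, d$list))()
    per_set <- cl_cols |>
      group_by(set = .data$set) |>
      summarise(
        n_clusters_significant = sum(.data$fdr < fdr_max, na.rm = TRUE),
        best_cluster = .data$list[which.max(.data$score)],
        .groups = "drop"
      ) |>
      filter(.data$n_clusters_significant >= 1L)
    if (nrow(per_set) == 0L) {
      return(base |> mutate(n_significant = 0L, mean_dispersion = NA_real_,
                            max_dispersion = NA_integer_,
                            min_cluster_size_at_max = NA_integer_,
                            per_set = list(per_set)))
    }
    base |> mutate(
      n_significant = nrow(per_set),
      mean_dispersion = mean(per_set$n_clusters_significant),
      max_dispersion = max(per_set$n_clusters_significant),
      min_cluster_size_at_max = min(sizes[per_set$best_cluster]),
      per_set = list(per_set)
    )
  })
  bind_rows(rows)
}
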
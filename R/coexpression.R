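#' Expression profiles of differentially expressed genes
#'
#' Bundles a genes-by-samples expression matrix with per-sample group labels
#' (e.g. lesional vs non-lesional) and per-gene regulation direction (the sign
#' of the upstream log fold-change). All clustering and enrichment starts from
#' this object.
#'
#' @param x numeric matrix (genes in rows, samples in columns) with rownames =
#'   gene identifiers and colnames = sample identifiers, or a data frame whose
#'   first column is the gene identifier.
#' @param sample_group character vector of per-sample group labels, named by
#'   sample or in column order.
#' @param regulation character vector of `"up"`/`"down"` per gene, named by
#'   gene or in row order.
#' @return An `expression_profile` object.
#' @export
expression_profile <- function(x, sample_group, regulation) {
  if (is.data.frame(x)) {
    ids <- norm_gene_ids(as.character(x[[1L]]))
    m <- as.matrix(x[-1L])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    assert_that(!is.null(rownames(m)), "matrix must have gene identifiers as rownames")
    rownames(m) <- norm_gene_ids(rownames(m))
  }
  assert_that(!is.null(colnames(m)), "expression input must carry sample identifiers")
  assert_that(!anyNA(m), "expression matrix contains missing values")
  assert_that(!anyDuplicated(rownames(m)), "gene identifiers must be unique")
  assert_that(!anyDuplicated(colnames(m)), "sample identifiers must be unique")
  assert_that(ncol(m) >= 3L, "need at least 3 samples (correlation metrics undefined below that)")

  sample_group <- as.character(sample_group)
  if (!is.null(names(sample_group))) {
    assert_that(setequal(names(sample_group), colnames(m)),
                "sample_group names do not match sample identifiers")
    sample_group <- sample_group[colnames(m)]
  } else {
    assert_that(length(sample_group) == ncol(m),
                "sample_group length must equal the number of samples")
    names(sample_group) <- colnames(m)
  }

  regulation <- as.character(regulation)
  if (!is.null(names(regulation))) {
    names(regulation) <- norm_gene_ids(names(regulation))
    assert_that(all(rownames(m) %in% names(regulation)),
                "regulation is missing entries for some genes")
    regulation <- regulation[rownames(m)]
  } else {
    assert_that(length(regulation) == nrow(m),
                "regulation length must equal the number of genes")
    names(regulation) <- rownames(m)
  }
  assert_that(all(regulation %in% c("up", "down")),
              "regulation must be 'up' or 'down' for every gene")

  structure(
    list(matrix = m, sample_group = sample_group, regulation = regulation),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples\n", sep = "")
  cat("  groups: ", paste(sprintf("%s (%d)", names(table(x$sample_group)),
                                  table(x$sample_group)), collapse = ", "), "\n",
      sep = "")
  cat("  regulation: ", sum(x$regulation == "up"), " up / ",
      sum(x$regulation == "down"), " down\n", sep = "")
  invisible(x)
}

#' @method as_tibble expression_profile
#' @export
as_tibble.expression_profile <- function(x, ...) {
  tibble(gene = rownames(x$matrix), regulation = unname(x$regulation)) |>
    dplyr::bind_cols(as_tibble(x$matrix))
}

#' Threshold a differential-expression statistics table
#'
#' Keeps genes with `FDR < fdr_max` and `|logFC| > abs_logfc_min` (both strict,
#' matching the conventional reporting of these thresholds) and assigns each
#' surviving gene a regulation direction from the sign of its log fold-change.
#'
#' @param stats data frame with columns `gene`, `logFC`, `FDR`.
#' @param fdr_max FDR threshold, default 0.05 (strict `<`).
#' @param abs_logfc_min absolute log fold-change threshold, default 1 (strict `>`).
#' @return A tibble `gene, logFC, FDR, regulation` of the genes passing both
#'   thresholds, in input order.
#' @export
filter_de <- function(stats, fdr_max = 0.05, abs_logfc_min = 1.0) {
  missing_cols <- setdiff(c("gene", "logFC", "FDR"), names(stats))
  if (length(missing_cols) > 0L) {
    abort(paste0("stats table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  assert_that(fdr_max > 0 && abs_logfc_min > 0, "thresholds must be positive")
  as_tibble(stats) |>
    mutate(gene = norm_gene_ids(.data$gene)) |>
    filter(.data$FDR < fdr_max, abs(.data$logFC) > abs_logfc_min) |>
    mutate(regulation = ifelse(.data$logFC > 0, "up", "down")) |>
    select("gene", "logFC", "FDR", "regulation")
}

#' Standardise expression rows
#'
#' Centres and scales every gene row to mean 0, sample standard deviation 1.
#' Idempotent up to numerical tolerance. Zero-variance genes are an error (a
#' constant gene carries no co-expression signal and breaks correlation
#' metrics).
#'
#' @param profile an [expression_profile()].
#' @return The profile with a standardised matrix.
#' @export
scale_rows <- function(profile) {
  m <- profile$matrix
  s <- apply(m, 1L, sd)
  zero <- rownames(m)[s == 0 | !is.finite(s)]
  if (length(zero) > 0L) {
    abort(paste0("zero-variance gene(s): ", paste(head(zero, 5L), collapse = ", ")))
  }
  profile$matrix <- (m - rowMeans(m)) / s
  profile
}

# ---- distance metrics --------------------------------------------------------

#' @rdname distance_matrix
#' @export
coex_metrics <- function() {
  c("euclidean", "pearson", "abs_pearson", "correlation", "abs_correlation",
    "spearman", "biwt")
}

# Biweight midcorrelation with tuning constant 9 (median/MAD based,
# Tukey bisquare weights). Rows of x are observations' variables.
bicor_matrix <- function(x, const = 9) {
  med <- apply(x, 1L, median)
  madv <- apply(x, 1L, mad, constant = 1)
  if (any(madv == 0)) {
    # fall back to mean/sd weights for rows with zero MAD, as is conventional
    madv[madv == 0] <- apply(x[madv == 0, , drop = FALSE], 1L, sd) / const
  }
  u <- (x - med) / (const * madv)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- (x - med) * w
  norm <- sqrt(rowSums(a^2))
  s <- tcrossprod(a / norm)
  pmin(pmax(s, -1), 1)
}

#' Gene-gene distance matrices
#'
#' Computes the symmetric genes-by-genes distance matrix under one of seven
#' metrics: `euclidean` (L2 on rows), `pearson` (1 minus the uncentred
#' correlation, i.e. the cosine of the raw rows), `correlation` (1 minus
#' centred Pearson r), `spearman` (1 minus Pearson r of within-row ranks,
#' average ranks for ties), `biwt` (1 minus biweight midcorrelation, tuning
#' constant 9), and `abs_pearson`/`abs_correlation` (1 minus the absolute
#' similarity). Correlation-family distances lie in \[0, 2\] (absolute
#' variants in \[0, 1\]).
#'
#' @param profile an [expression_profile()] with at least 2 genes.
#' @param metric one of `coex_metrics()` (or `"manhattan"`, accepted for the
#'   CLARA method only).
#' @return Symmetric numeric matrix with zero diagonal and a `"metric"`
#'   attribute.
#' @export
distance_matrix <- function(profile, metric = "correlation") {
  metric <- match.arg(metric, c(coex_metrics(), "manhattan"))
  x <- profile$matrix
  assert_that(nrow(x) >= 2L, "need at least 2 genes")
  if (!metric %in% c("euclidean", "manhattan") && ncol(x) < 3L) {
    abort("correlation-family metrics need at least 3 samples")
  }
  d <- switch(
    metric,
    euclidean = as.matrix(dist(x, method = "euclidean")),
    manhattan = as.matrix(dist(x, method = "manhattan")),
    pearson = {
      s <- tcrossprod(x) / sqrt(outer(rowSums(x^2), rowSums(x^2)))
      1 - pmin(pmax(s, -1), 1)
    },
    abs_pearson = {
      s <- tcrossprod(x) / sqrt(outer(rowSums(x^2), rowSums(x^2)))
      1 - abs(pmin(pmax(s, -1), 1))
    },
    correlation = 1 - cor(t(x)),
    abs_correlation = 1 - abs(cor(t(x))),
    spearman = 1 - cor(t(x), method = "spearman"),
    biwt = 1 - bicor_matrix(x)
  )
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "metric") <- metric
  d
}

#' Resolve a distance metric against a clustering method's capabilities
#'
#' Not every clustering method supports every metric; incompatible requests
#' fall back deterministically: k-means turns `biwt` into `correlation`; CLARA
#' keeps `euclidean` (or an explicit `manhattan`) and turns everything else
#' into `euclidean`; SOTA keeps `correlation` and `euclidean` and turns
#' everything else into `correlation`; SOM always uses `euclidean`; the
#' model-based method uses its own likelihood and ignores the metric
#' (resolved to `"model"`). Fully-compatible methods (hierarchical, agnes,
#' diana, fanny, pam) pass the metric through. The function is total and
#' idempotent; callers log every substitution.
#'
#' @param method one of [coex_methods()].
#' @param metric one of `coex_metrics()`, `"manhattan"` (CLARA only), or a
#'   previously resolved value.
#' @return The metric actually used.
#' @export
resolve_metric <- function(method, metric = "correlation") {
  method <- match.arg(method, coex_methods())
  if (method == "model" && identical(metric, "model")) return("model")
  metric <- match.arg(metric, c(coex_metrics(), "manhattan"))
  if (metric == "manhattan" && method != "clara") {
    abort("metric 'manhattan' is only accepted for method 'clara'")
  }
  switch(
    method,
    hierarchical = , agnes = , diana = , fanny = , pam = metric,
    kmeans = if (metric == "biwt") "correlation" else metric,
    clara = if (metric %in% c("euclidean", "manhattan")) metric else "euclidean",
    sota = if (metric %in% c("correlation", "euclidean")) metric else "correlation",
    som = "euclidean",
    model = "model"
  )
}
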
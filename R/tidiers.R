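#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster assignment
#'
#' @param x a `cluster_assignment` from [coex_cluster()].
#' @param ... unused.
#' @return A tibble `gene, cluster, regulation`-free long form (one row per
#'   gene).
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(gene = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.cluster_assignment
#' @return For `glance`: a one-row tibble of fit metadata (`method`,
#'   `k_requested`, `k_found`, `metric_requested`, `metric_used`, `seed`,
#'   `n_genes`, `notes`).
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(method = x$method, k_requested = x$k_requested, k_found = x$k_found,
         metric_requested = x$metric_requested, metric_used = x$metric_used,
         seed = x$seed, n_genes = length(x$labels),
         notes = paste(x$notes, collapse = "; "))
}

#' Tidy an enrichment table
#'
#' @param x an `enrichment_tbl` from [enrich()] or [reposition()].
#' @param ... unused.
#' @return The long tibble of cells (`set, list, n, m, k, N, p_raw, fdr,
#'   score, capped`, plus instance metadata for repositioning tables).
#' @method tidy enrichment_tbl
#' @export
tidy.enrichment_tbl <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.enrichment_tbl
#' @param fdr_max significance threshold used by `glance` (default 0.05).
#' @return For `glance`: one row per gene-list column with the number of sets
#'   tested, significant at `fdr_max`, and the best set.
#' @method glance enrichment_tbl
#' @export
glance.enrichment_tbl <- function(x, fdr_max = 0.05, ...) {
  as_tibble(x) |>
    group_by(list = .data$list) |>
    summarise(
      n_sets = n(),
      n_significant = sum(.data$fdr < fdr_max, na.rm = TRUE),
      best_set = if (all(is.na(.data$score))) NA_character_
                 else .data$set[which.max(.data$score)],
      best_score = if (all(is.na(.data$score))) NA_real_
                   else max(.data$score, na.rm = TRUE),
      .groups = "drop"
    )
}
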
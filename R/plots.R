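#' @importFrom ggplot2 ggplot aes geom_tile geom_raster scale_fill_gradient2
#'   scale_fill_gradient labs theme_minimal theme element_text element_blank
#'   autoplot ggsave facet_grid scale_y_discrete
NULL

direction_palette <- function(colourblind_safe = TRUE) {
  if (colourblind_safe) {
    c(up = "#D55E00", down = "#0072B2", mixed = "#999999", all = "#0072B2")
  } else {
    c(up = "red", down = "green4", mixed = "grey40", all = "blue")
  }
}

#' Expression heatmap with numbered clusters
#'
#' Genes are ordered cluster-contiguously (clusters numbered by descending
#' size for display; enrichment scores are invariant to relabelling) and each
#' gene's up/down regulation is shown in a bar on the far left.
#'
#' @param profile an [expression_profile()].
#' @param assignment a `cluster_assignment` from [coex_cluster()].
#' @param scale_rows_first standardise rows before plotting (default TRUE).
#' @return A ggplot object; the gene order used is stored in
#'   `attr(, "gene_order")`.
#' @export
plot_expression_heatmap <- function(profile, assignment,
                                    scale_rows_first = TRUE) {
  if (scale_rows_first) profile <- scale_rows(profile)
  sizes <- sort(table(assignment$labels), decreasing = TRUE)
  display_no <- setNames(seq_along(sizes), names(sizes))
  ord_tbl <- tibble(
    gene = names(assignment$labels),
    cluster = unname(display_no[as.character(assignment$labels)])
  ) |> arrange(.data$cluster, .data$gene)
  long <- as.data.frame(profile$matrix[ord_tbl$gene, , drop = FALSE]) |>
    tibble::rownames_to_column("gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "z") |>
    mutate(gene = factor(.data$gene, levels = rev(ord_tbl$gene)))
  p <- ggplot(long, aes(x = .data$sample, y = .data$gene, fill = .data$z)) +
    geom_raster() +
    scale_fill_gradient2(low = "#0072B2", mid = "white", high = "#D55E00") +
    labs(x = NULL, y = NULL, fill = "z-score",
         title = paste0("Co-expression clusters (", assignment$method,
                        ", k = ", assignment$k_found, ")")) +
    theme_minimal(base_size = 8) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5),
          axis.text.y = element_blank())
  attr(p, "gene_order") <- ord_tbl
  p
}

#' Enrichment-score heatmap
#'
#' Rows are gene sets ordered by [rank_sets()]; columns are the cluster lists
#' plus "up", "down" and "all"; fill depth is the `-log2(FDR)` score. Column
#' labels are conventionally coloured by list direction (up/down/all).
#'
#' @param table an `enrichment_tbl`.
#' @param rank_mode ranking mode passed to [rank_sets()] (default "mean").
#' @param top show only the `top` ranked sets (default 20; `Inf` for all).
#' @return A ggplot object; the row order is stored in `attr(, "set_order")`.
#' @export
plot_enrichment_heatmap <- function(table, rank_mode = "mean", top = 20) {
  ranked <- rank_sets(table, rank_mode)
  keep <- head(ranked$set, top)
  dirs <- attr(table, "list_directions")
  # direction is carried in the column label (e.g. "3 [up]"), the analogue of
  # colouring up-regulated cluster labels red and down-regulated green
  label_of <- function(l) {
    d <- dirs[[l]] %||% "mixed"
    if (l %in% c("up", "down", "all")) l else paste0(l, " [", d, "]")
  }
  long <- as_tibble(table) |>
    filter(.data$set %in% keep) |>
    mutate(score = tidyr::replace_na(.data$score, 0),
           set = factor(.data$set, levels = rev(keep)),
           list = factor(vapply(as.character(.data$list), label_of,
                                character(1)),
                         levels = vapply(unique(as.character(.data$list)),
                                         label_of, character(1))))
  p <- ggplot(long, aes(x = .data$list, y = .data$set, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#CC3311") +
    labs(x = "gene list", y = NULL, fill = "-log2(FDR)",
         title = paste0("Gene-set enrichment (ranked by ", rank_mode, ")")) +
    theme_minimal(base_size = 8) +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  attr(p, "set_order") <- keep
  p
}

#' Merged drug-repositioning heatmap
#'
#' Rows compose the merged drug group with its passing-instance count;
#' columns are the gene lists.
#'
#' @param merged a `merged_enrichment` from [merge_instances()].
#' @return A ggplot object (an informative empty plot if nothing passed the
#'   merge threshold); row count is stored in `attr(, "n_rows")`.
#' @export
plot_drug_heatmap <- function(merged) {
  if (nrow(merged) == 0L) {
    p <- ggplot() +
      labs(title = "No drug group passed the merge threshold") +
      theme_minimal()
    attr(p, "n_rows") <- 0L
    return(p)
  }
  long <- merged |>
    mutate(row_label = paste0(.data$group_key, " [", .data$direction, "] (n=",
                              .data$n_instances, ")"),
           score = tidyr::replace_na(.data$score, 0))
  row_levels <- long |>
    group_by(.data$row_label) |>
    summarise(s = max(.data$score), .groups = "drop") |>
    arrange(.data$s) |>
    dplyr::pull(.data$row_label)
  long <- long |> mutate(row_label = factor(.data$row_label, levels = row_levels))
  p <- ggplot(long, aes(x = .data$list, y = .data$row_label,
                        fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#CC3311") +
    labs(x = "gene list", y = NULL, fill = "-log2(FDR)",
         title = "Merged drug repositioning candidates") +
    theme_minimal(base_size = 8)
  attr(p, "n_rows") <- length(row_levels)
  p
}

#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, rank_mode = "mean", ...) {
  plot_enrichment_heatmap(object, rank_mode = rank_mode, ...)
}

#' @method autoplot merged_enrichment
#' @export
autoplot.merged_enrichment <- function(object, ...) {
  plot_drug_heatmap(object)
}
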
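#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `m` are
#' annotated:
#' \deqn{P(X \ge k) = \sum_{x=k}^{\min(m,n)} \binom{m}{x}\binom{N-m}{n-x} / \binom{N}{n}.}
#' Terms are accumulated in log space (`lchoose` + log-sum-exp) so small tail
#' probabilities are computed stably. `k = 0` returns exactly 1.
#'
#' @param k,m,n,N non-negative integers (vectorised) with `m <= N`, `n <= N`,
#'   `k <= min(m, n)`.
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, m, n, N) {
  args <- cbind(k = k, m = m, n = n, N = N)
  k <- args[, "k"]; m <- args[, "m"]; n <- args[, "n"]; N <- args[, "N"]
  bad <- k < 0 | m < 0 | n < 0 | N < 0 | m > N | n > N | k > pmin(m, n) |
    args != floor(args)
  if (any(bad)) {
    abort("need non-negative integers with m <= N, n <= N, k <= min(m, n)")
  }
  vapply(seq_along(k), function(i) {
    if (k[i] == 0) return(1)
    x <- seq.int(k[i], min(m[i], n[i]))
    lp <- lchoose(m[i], x) + lchoose(N[i] - m[i], n[i] - x) - lchoose(N[i], n[i])
    mx <- max(lp)
    min(exp(mx + log(sum(exp(lp - mx)))), 1)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' the adjusted value at rank i is `min over j >= i of p_(j) * M / j`, clipped
#' to 1, returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && !anyNA(p) && all(p >= 0 & p <= 1),
              "p-values must be numeric in [0, 1]")
  p.adjust(p, method = "BH")
}

# -log2(fdr) with an underflow floor at the smallest positive normalised
# double; capped scores are flagged so callers can log the event.
SCORE_FLOOR <- .Machine$double.xmin

enrichment_score <- function(fdr) {
  -log2(pmax(fdr, SCORE_FLOOR))
}

#' Hypergeometric enrichment of gene lists against a collection
#'
#' Tests every (gene set, gene list) pair: both sides are intersected with
#' the background universe, the overlap is scored with
#' [hypergeom_upper_tail()], and BH correction is applied per gene-list
#' column across all sets in the collection (each column is the hypothesis
#' family "which sets match this cluster"). The enrichment score is
#' `-log2(FDR)`, floored against underflow. A list with no background
#' overlap yields absent (`NA`) cells, not zeros.
#'
#' @param lists a tibble from [gene_lists()] (columns `label`, `genes`,
#'   `direction`), or any tibble with those columns.
#' @param collection a [gene_set_collection()].
#' @param background character vector of gene identifiers to use as the
#'   universe N. Defaults to the collection universe; supply the platform's
#'   measured genes when available — N materially changes p-values.
#' @return An `enrichment_tbl`: long tibble `set, list, n, m, k, N, p_raw,
#'   fdr, score, capped` with list directions and the background size kept as
#'   attributes. See [score_matrix()] for the wide form.
#' @export
enrich <- function(lists, collection, background = NULL) {
  collection <- validate_gene_set_collection(collection)
  assert_that(nrow(lists) > 0L, "no gene lists supplied")
  background <- unique(norm_gene_ids(background %||% gs_universe(collection)))
  N <- length(background)

  sets_bg <- lapply(collection$genes, intersect, y = background)
  m <- lengths(sets_bg)

  cols <- lapply(seq_len(nrow(lists)), function(i) {
    q <- intersect(unique(norm_gene_ids(lists$genes[[i]])), background)
    n_q <- length(q)
    if (n_q == 0L) {
      return(tibble(set = collection$name, list = lists$label[i],
                    n = NA_integer_, m = as.integer(m), k = NA_integer_,
                    N = N, p_raw = NA_real_, fdr = NA_real_,
                    score = NA_real_, capped = NA))
    }
    k <- vapply(sets_bg, function(s) length(intersect(s, q)), integer(1))
    p <- hypergeom_upper_tail(k, m, n_q, N)
    fdr <- bh_adjust(p)
    tibble(set = collection$name, list = lists$label[i],
           n = n_q, m = as.integer(m), k = as.integer(k), N = N,
           p_raw = p, fdr = fdr, score = enrichment_score(fdr),
           capped = fdr < SCORE_FLOOR)
  })
  out <- bind_rows(cols)
  new_enrichment_tbl(out, lists, N)
}

new_enrichment_tbl <- function(tbl, lists, N) {
  attr(tbl, "list_directions") <- setNames(lists$direction, lists$label)
  attr(tbl, "background_n") <- N
  class(tbl) <- c("enrichment_tbl", class(tibble()))
  tbl
}

#' Wide score matrix of an enrichment table
#'
#' @param table an `enrichment_tbl` from [enrich()] or [reposition()].
#' @param fill value for absent cells (default 0, matching how heatmaps
#'   render them).
#' @return A tibble: one row per set, one column per gene list, values =
#'   enrichment scores.
#' @export
score_matrix <- function(table, fill = 0) {
  table |>
    as_tibble() |>
    select("set", "list", "score") |>
    tidyr::pivot_wider(names_from = "list", values_from = "score",
                       values_fill = fill) |>
    mutate(across(-"set", ~ tidyr::replace_na(.x, fill)))
}

#' Rank gene sets by enrichment
#'
#' `mean`/`max` aggregate each set's scores over the cluster columns plus the
#' `"all"` column (absent cells count as 0); `"all"`, `"up"`, `"down"` or a
#' cluster index rank by that single column. Descending score, ties broken
#' lexicographically by set name.
#'
#' @param table an `enrichment_tbl`.
#' @param mode `"mean"`, `"max"`, `"all"`, `"up"`, `"down"`, or a cluster
#'   index (integer or its string form).
#' @return A tibble `set, rank_score, rank` in rank order.
#' @export
rank_sets <- function(table, mode = "mean") {
  mode <- as.character(mode)
  tbl <- as_tibble(table)
  cols <- unique(tbl$list)
  cluster_cols <- setdiff(cols, c("up", "down"))  # clusters plus "all"
  scores <-
    if (mode %in% c("mean", "max")) {
      agg <- if (mode == "mean") mean else max
      tbl |>
        filter(.data$list %in% cluster_cols) |>
        mutate(score = tidyr::replace_na(.data$score, 0)) |>
        group_by(set = .data$set) |>
        summarise(rank_score = agg(.data$score), .groups = "drop")
    } else {
      if (!mode %in% cols) {
        abort(paste0("no gene-list column '", mode, "' in this table"))
      }
      tbl |>
        filter(.data$list == mode) |>
        mutate(score = tidyr::replace_na(.data$score, 0)) |>
        select(set = "set", rank_score = "score")
    }
  scores |>
    arrange(desc(.data$rank_score), .data$set) |>
    mutate(rank = row_number())
}

#' Drug repositioning by directional signature matching
#'
#' Tests co-expressed gene lists against directional drug-perturbation
#' signature sets. Under the default `orientation = "inverse"` — the
#' repositioning hypothesis that a therapeutic drug reverses the disease
#' signature — up-regulated gene lists are tested only against drugs'
#' down-regulated sets and vice versa; `"mixed"` lists are tested against
#' both directions. `orientation = "same"` matches directions instead
#' (useful to flag drugs that might induce the phenotype, e.g. as a side
#' effect), and `"both"` applies no filter. BH correction runs per column
#' across the sets actually tested in that column.
#'
#' @param lists a tibble from [gene_lists()].
#' @param drug_collection a [gene_set_collection()] whose set names parse
#'   with [parse_instance_name()].
#' @param background gene universe (default: collection universe).
#' @param orientation `"inverse"`, `"same"`, or `"both"`.
#' @return An `enrichment_tbl` restricted to the tested (set, list) pairs,
#'   with instance metadata columns (`compound`, `cell_type`,
#'   `concentration`, `instance`, `set_direction`).
#' @export
reposition <- function(lists, drug_collection, background = NULL,
                       orientation = c("inverse", "same", "both")) {
  orientation <- match.arg(orientation)
  drug_collection <- validate_gene_set_collection(drug_collection)
  meta <- parse_instance_name(drug_collection$name)  # errors if unparseable
  background <- unique(norm_gene_ids(background %||% gs_universe(drug_collection)))
  N <- length(background)
  sets_bg <- lapply(drug_collection$genes, intersect, y = background)
  m_all <- lengths(sets_bg)

  wanted_dirs <- function(list_dir) {
    switch(orientation,
           both = c("up", "down"),
           inverse = if (list_dir == "mixed") c("up", "down")
                     else setdiff(c("up", "down"), list_dir),
           same = if (list_dir == "mixed") c("up", "down") else list_dir)
  }

  cols <- lapply(seq_len(nrow(lists)), function(i) {
    keep <- meta$direction %in% wanted_dirs(lists$direction[i])
    if (!any(keep)) return(NULL)
    q <- intersect(unique(norm_gene_ids(lists$genes[[i]])), background)
    n_q <- length(q)
    if (n_q == 0L) {
      return(tibble(set = drug_collection$name[keep], list = lists$label[i],
                    n = NA_integer_, m = as.integer(m_all[keep]),
                    k = NA_integer_, N = N, p_raw = NA_real_, fdr = NA_real_,
                    score = NA_real_, capped = NA))
    }
    k <- vapply(sets_bg[keep], function(s) length(intersect(s, q)), integer(1))
    p <- hypergeom_upper_tail(k, m_all[keep], n_q, N)
    fdr <- bh_adjust(p)
    tibble(set = drug_collection$name[keep], list = lists$label[i],
           n = n_q, m = as.integer(m_all[keep]), k = as.integer(k), N = N,
           p_raw = p, fdr = fdr, score = enrichment_score(fdr),
           capped = fdr < SCORE_FLOOR)
  })
  out <- bind_rows(cols) |>
    left_join(meta |> dplyr::rename(set = "set_name",
                                    set_direction = "direction"),
              by = "set")
  new_enrichment_tbl(out, lists, N)
}

#' Merge multi-instance drug enrichments
#'
#' Drugs profiled in several instances (cell line x concentration replicates)
#' give one directional set per instance. Within each group defined by the
#' `by` fields (see [group_instances()]), instances whose score reaches
#' `threshold` in a given gene-list column are aggregated by `mean` or `max`;
#' the per-cell instance count is retained. Groups in which no instance
#' passes the threshold in any column are dropped.
#'
#' @param table an `enrichment_tbl` from [reposition()].
#' @param threshold minimum score for an instance to contribute; default
#'   `-log2(0.05)`, i.e. FDR 0.05 on the score scale.
#' @param by instance-key fields to merge over (default `"compound"`).
#' @param aggregator `"mean"` or `"max"`.
#' @return A `merged_enrichment` tibble: `group_key`, the `by` fields,
#'   `direction`, `list`, merged `score`, `n_instances` passing, and
#'   `n_instances_total` in the group.
#' @export
merge_instances <- function(table, threshold = -log2(0.05), by = "compound",
                            aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  tbl <- as_tibble(table)
  if (nrow(tbl) == 0L) return(tbl)
  assert_that(all(c("compound", "set_direction") %in% names(tbl)),
              "table lacks drug-instance metadata; run reposition() first")
  agg_fun <- if (aggregator == "mean") mean else max
  allowed <- c("compound", "cell_type", "concentration", "instance")
  assert_that(all(by %in% allowed), "invalid 'by' field")

  grouped <- tbl |>
    mutate(compound = tolower(.data$compound)) |>
    group_by(across(all_of(c(by, "set_direction", "list")))) |>
    summarise(
      n_instances = sum(!is.na(.data$score) & .data$score >= threshold),
      n_instances_total = n(),
      score = {
        s <- .data$score[!is.na(.data$score) & .data$score >= threshold]
        if (length(s)) agg_fun(s) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::rename(direction = "set_direction")
  grouped$group_key <- do.call(paste, c(grouped[by], list(sep = INSTANCE_SEP)))
  keep_keys <- grouped |>
    group_by(.data$group_key, .data$direction) |>
    summarise(any_pass = any(.data$n_instances > 0L), .groups = "drop") |>
    filter(.data$any_pass)
  out <- grouped |>
    dplyr::semi_join(keep_keys, by = c("group_key", "direction")) |>
    select("group_key", all_of(by), "direction", "list", "score",
           "n_instances", "n_instances_total")
  class(out) <- c("merged_enrichment", class(tibble()))
  out
}
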
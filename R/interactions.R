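#' Undirected interaction networks
#'
#' A light container for a protein-protein (or any gene-gene) interaction
#' network: unique undirected edges, no self-loops, per-node degree and the
#' total edge count M.
#'
#' @param edges a data frame whose first two columns are node identifiers of
#'   the interacting pair.
#' @return An `interaction_network` object with fields `edges` (tibble
#'   `from`, `to`, with `from < to`), `nodes`, `degree` (named integer) and
#'   `M`.
#' @export
interaction_network <- function(edges) {
  assert_that(ncol(edges) >= 2L, "edge input needs two columns")
  a <- norm_gene_ids(as.character(edges[[1L]]))
  b <- norm_gene_ids(as.character(edges[[2L]]))
  self <- a == b
  n_self <- sum(self)
  if (n_self > 0L) {
    inform(paste0("dropped ", n_self, " self-loop(s)"))
  }
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  e <- distinct(tibble(from = a2, to = b2))
  assert_that(nrow(e) > 0L, "network has no edges after cleaning")
  nodes <- sort(unique(c(e$from, e$to)))
  deg <- table(factor(c(e$from, e$to), levels = nodes))
  structure(
    list(edges = e, nodes = nodes,
         degree = setNames(as.integer(deg), nodes),
         M = nrow(e), n_self_loops_dropped = n_self),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", length(x$nodes), " nodes, ", x$M, " edges\n",
      sep = "")
  invisible(x)
}

#' Read an interaction network from a two-column edge list
#'
#' Whitespace- or tab-separated pairs, one edge per line; duplicate and
#' reversed pairs collapse to one undirected edge; self-loops are dropped
#' (and counted in the returned object).
#'
#' @param path path to the edge-list file.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  tbl <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      col.names = c("from", "to")),
    error = function(e) abort(paste0("cannot parse edge list ", path, ": ",
                                     conditionMessage(e)))
  )
  assert_that(nrow(tbl) > 0L, paste0("empty edge list: ", path))
  interaction_network(tbl)
}

#' Observed edges within a gene list
#'
#' Number of network edges with both endpoints in the list. Genes absent
#' from the network are ignored.
#'
#' @param net an [interaction_network()].
#' @param genes character vector of gene identifiers.
#' @return Integer edge count.
#' @export
observed_edges <- function(net, genes) {
  genes <- unique(norm_gene_ids(genes))
  sum(net$edges$from %in% genes & net$edges$to %in% genes)
}

#' Expected edges within a gene list under a degree-preserving null
#'
#' Expectation of the intra-list edge count when edges are rewired at random
#' while preserving every node's degree (Chung-Lu form): for list nodes i < j,
#' \deqn{E = \sum_{i<j} \min(1, d_i d_j / 2M).}
#' Genes absent from the network contribute nothing.
#'
#' @param net an [interaction_network()].
#' @param genes character vector of gene identifiers.
#' @return Expected edge count (non-negative real).
#' @export
expected_edges <- function(net, genes) {
  genes <- intersect(unique(norm_gene_ids(genes)), net$nodes)
  if (length(genes) < 2L) return(0)
  d <- as.numeric(net$degree[genes])
  p <- outer(d, d) / (2 * net$M)
  p[p > 1] <- 1
  sum(p[upper.tri(p)])
}

#' Tail p-value for intra-list connectivity
#'
#' Probability of seeing at least the observed number of intra-list edges by
#' chance, with the null count modelled as Poisson with mean equal to the
#' degree-preserving expectation: `P(X >= observed | lambda = expected)`.
#' `observed = 0` returns 1.
#'
#' @param observed integer observed edge count.
#' @param expected expected edge count (>= 0).
#' @return p-value in (0, 1].
#' @export
connectivity_pvalue <- function(observed, expected) {
  assert_that(all(expected >= 0) && all(observed >= 0),
              "observed and expected must be non-negative")
  ifelse(observed == 0, 1,
         ppois(observed - 1, lambda = expected, lower.tail = FALSE))
}

#' Ratio of observed to expected connectivity
#'
#' @param observed observed intra-list edge count.
#' @param expected expected count under the degree-preserving null.
#' @param digits if non-NULL, round half-up for display, matching the
#'   convention of published interaction-summary tables (the underlying
#'   summary stores full precision).
#' @return `observed / expected`, or `NA` when `expected` is 0.
#' @export
connectivity_ratio <- function(observed, expected, digits = NULL) {
  r <- ifelse(expected > 0, observed / expected, NA_real_)
  if (!is.null(digits)) r <- floor(r * 10^digits + 0.5) / 10^digits
  r
}

#' Connectivity summary per gene list
#'
#' For each gene list (clusters plus "up", "down", "all"): how many genes it
#' holds, how many map into the network, the observed intra-list edge count,
#' the degree-preserving expectation, their ratio (NA when the expectation is
#' 0; `ratio_display` rounds to 2 decimals for reporting) and the Poisson
#' upper-tail p-value.
#'
#' @param net an [interaction_network()].
#' @param lists a tibble from [gene_lists()] (columns `label`, `genes`).
#' @return A tibble with one row per list.
#' @export
connectivity_summary <- function(net, lists) {
  rows <- lapply(seq_len(nrow(lists)), function(i) {
    g <- unique(norm_gene_ids(lists$genes[[i]]))
    mapped <- intersect(g, net$nodes)
    obs <- observed_edges(net, mapped)
    exp_ <- expected_edges(net, mapped)
    tibble(
      list_label = lists$label[i],
      genes_in_list = length(g),
      nodes_mapped = length(mapped),
      observed = obs,
      expected = exp_,
      ratio = connectivity_ratio(obs, exp_),
      ratio_display = connectivity_ratio(obs, exp_, digits = 2),
      p_value = connectivity_pvalue(obs, exp_)
    )
  })
  bind_rows(rows)
}
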
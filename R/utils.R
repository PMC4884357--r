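#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join distinct n desc across all_of row_number
#' @importFrom stats cor dist sd phyper ppois p.adjust kmeans cutree hclust
#'   as.hclust mad median rnorm runif t.test setNames
#' @importFrom utils head tail
NULL

# Normalise gene identifiers: trim whitespace, upper-case.
norm_gene_ids <- function(x) toupper(trimws(x))

# Deterministic per-task RNG stream derived from (seed, method, k).
# Simple multiplicative hash kept below 2^31 so it is a valid R seed.
derive_seed <- function(seed, method, k) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(paste0(method, "|", k))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%theni%` <- function(x, y) if (length(x) == 0L) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
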
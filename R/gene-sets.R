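#' Gene-set collections
#'
#' A gene-set collection is a tibble with one row per set and columns
#' `name` (unique, non-empty), `description` (possibly empty string) and
#' `genes` (a list-column of unique, upper-cased gene identifiers). This is
#' the in-memory form of a GMT file and the unit passed to [enrich()] and
#' [reposition()].
#'
#' @param name character vector of set names.
#' @param description character vector of set descriptions (recycled).
#' @param genes list of character vectors, one per set.
#' @return A `gene_set_collection` tibble.
#' @examples
#' gene_set_collection(
#'   name = c("SETA", "SETB"),
#'   description = "",
#'   genes = list(c("TP53", "MYC"), c("EGFR", "KRAS", "MYC"))
#' )
#' @export
gene_set_collection <- function(name, description = "", genes) {
  if (!is.list(genes)) genes <- list(genes)
  tbl <- tibble(
    name = as.character(name),
    description = as.character(description),
    genes = lapply(genes, function(g) unique(norm_gene_ids(g)))
  )
  validate_gene_set_collection(tbl)
}

validate_gene_set_collection <- function(tbl) {
  assert_that(nrow(tbl) > 0L, "a gene-set collection must contain at least one set")
  assert_that(all(nzchar(tbl$name)), "set names must be non-empty")
  dup <- tbl$name[duplicated(tbl$name)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate set names: ", paste(unique(dup), collapse = ", ")))
  }
  empty <- tbl$name[lengths(tbl$genes) == 0L]
  if (length(empty) > 0L) {
    abort(paste0("sets with no members: ", paste(empty, collapse = ", ")))
  }
  class(tbl) <- c("gene_set_collection", class(tibble()))
  tbl
}

#' Universe of a gene-set collection
#'
#' The exact union of all member genes across the collection's sets.
#'
#' @param collection a [gene_set_collection()].
#' @return Character vector of unique gene identifiers.
#' @export
gs_universe <- function(collection) {
  unique(unlist(collection$genes, use.names = FALSE))
}

#' Read a GMT file
#'
#' Gene Matrix Transposed format: one set per line, tab-separated fields
#' `name`, `description`, then one or more gene identifiers. Gene identifiers
#' are upper-cased and de-duplicated preserving first occurrence.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0L, paste0("empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(paste0(
      "malformed GMT line ", bad[1L], " in ", path,
      ": expected >= 3 tab-separated fields, got ", lengths(fields)[bad[1L]]
    ))
  }
  gene_set_collection(
    name = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path))` reproduces the
#' collection's names, descriptions and member sets. Refuses to write an
#' empty collection.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- validate_gene_set_collection(collection)
  lines <- vapply(
    seq_len(nrow(collection)),
    function(i) {
      paste(
        c(collection$name[i], collection$description[i], collection$genes[[i]]),
        collapse = "\t"
      )
    },
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- drug-instance set names -------------------------------------------------
# A directional drug-signature set is named
#   compound@cell_type@concentration@instance#up   (or #down)
# so that the instance key round-trips losslessly through the GMT name field.

INSTANCE_SEP <- "@"
DIRECTION_SEP <- "#"

#' Encode a drug-instance key as a set name
#'
#' @param compound,cell_type,concentration,instance character scalars or
#'   vectors (concentration kept verbatim, units embedded).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of set names.
#' @seealso [parse_instance_name()]
#' @export
encode_instance_name <- function(compound, cell_type, concentration, instance,
                                 direction) {
  assert_that(all(direction %in% c("up", "down")),
              "direction must be 'up' or 'down'")
  fields <- cbind(compound, cell_type, concentration, instance)
  if (any(grepl("[@#]", fields))) {
    abort("instance key fields must not contain '@' or '#'")
  }
  paste0(
    compound, INSTANCE_SEP, cell_type, INSTANCE_SEP, concentration,
    INSTANCE_SEP, instance, DIRECTION_SEP, direction
  )
}

#' Parse drug-instance set names
#'
#' Decodes the `compound@cell_type@concentration@instance#direction` set-name
#' dialect produced by [build_signature_sets()].
#'
#' @param set_name character vector of set names.
#' @return A tibble with columns `set_name`, `compound`, `cell_type`,
#'   `concentration`, `instance`, `direction`.
#' @export
parse_instance_name <- function(set_name) {
  parts <- strsplit(set_name, DIRECTION_SEP, fixed = TRUE)
  bad <- set_name[lengths(parts) != 2L |
                    !vapply(parts, function(p) p[2L] %in% c("up", "down"), logical(1))]
  if (length(bad) > 0L) {
    abort(paste0(
      "set names without a '#up'/'#down' direction suffix: ",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  stem <- vapply(parts, `[[`, character(1), 1L)
  direction <- vapply(parts, `[[`, character(1), 2L)
  fields <- strsplit(stem, INSTANCE_SEP, fixed = TRUE)
  bad <- set_name[lengths(fields) != 4L]
  if (length(bad) > 0L) {
    abort(paste0(
      "set names must have 4 '@'-separated fields before the direction: ",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  tibble(
    set_name = set_name,
    compound = vapply(fields, `[[`, character(1), 1L),
    cell_type = vapply(fields, `[[`, character(1), 2L),
    concentration = vapply(fields, `[[`, character(1), 3L),
    instance = vapply(fields, `[[`, character(1), 4L),
    direction = direction
  )
}

#' Build directional signature sets from a ranked profile
#'
#' Takes a treatment instance's genes ranked from most up- to most
#' down-regulated and extracts the top `top_n` as the "up" set and the bottom
#' `top_n` as the "down" set (stored most-down-regulated first). Membership
#' depends only on rank order, never on score magnitudes; the caller supplies
#' the total order.
#'
#' @param ranked_genes character vector of unique gene identifiers, ordered
#'   from most up-regulated to most down-regulated; length must be at least
#'   `2 * top_n`.
#' @param compound,cell_type,concentration,instance strings identifying the
#'   treatment instance.
#' @param top_n number of genes per directional set (default 100).
#' @return A [gene_set_collection()] of two sets (up, down), named via
#'   [encode_instance_name()].
#' @export
build_signature_sets <- function(ranked_genes, compound, cell_type,
                                 concentration, instance, top_n = 100L) {
  ranked_genes <- norm_gene_ids(ranked_genes)
  assert_that(top_n >= 1L, "top_n must be a positive integer")
  if (anyDuplicated(ranked_genes)) {
    abort("ranked profile contains duplicate genes")
  }
  if (length(ranked_genes) < 2L * top_n) {
    abort(paste0(
      "ranked profile has ", length(ranked_genes),
      " genes; need at least 2 * top_n = ", 2L * top_n
    ))
  }
  up <- ranked_genes[seq_len(top_n)]
  down <- rev(tail(ranked_genes, top_n))
  gene_set_collection(
    name = encode_instance_name(compound, cell_type, concentration, instance,
                                c("up", "down")),
    description = paste(compound, cell_type, concentration, instance),
    genes = list(up, down)
  )
}

#' Group drug-signature sets by instance-key fields
#'
#' Partitions the sets of a collection by a subset of the instance-key fields
#' (plus direction, which always separates groups), e.g. to merge instances of
#' the same compound observed in different cell lines.
#'
#' @param collection a [gene_set_collection()] whose set names parse with
#'   [parse_instance_name()].
#' @param by character subset of `c("compound", "cell_type", "concentration",
#'   "instance")`.
#' @return A tibble with the `by` columns, `direction`, `group_key`, and a
#'   `set_names` list-column; set names form a partition of the collection.
#' @export
group_instances <- function(collection, by = "compound") {
  allowed <- c("compound", "cell_type", "concentration", "instance")
  assert_that(length(by) > 0L && all(by %in% allowed),
              paste0("'by' must be a non-empty subset of: ",
                     paste(allowed, collapse = ", ")))
  meta <- parse_instance_name(collection$name)
  meta$compound <- tolower(meta$compound)  # compounds compared case-insensitively
  grp <- meta |>
    group_by(across(all_of(c(by, "direction")))) |>
    summarise(set_names = list(set_name), n_instances = n(), .groups = "drop")
  grp$group_key <- do.call(paste, c(grp[by], list(sep = INSTANCE_SEP)))
  grp |>
    select(all_of(by), "direction", "group_key", "set_names", "n_instances")
}

#' @importFrom rlang .data
NULL
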
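#' The eight harmonized taxonomy ranks
#'
#' Every taxonomy attached to a compound record is normalized to exactly
#' these ranks, in this order, with blanks (`""`) where a level is
#' unknown.
#'
#' @return Character vector of the eight rank names.
#' @export
taxonomy_ranks <- function() {
  c("SuperKingdom", "Kingdom", "Phylum", "Class", "Order",
    "Family", "Genus", "Species")
}

# rank-name aliases seen across source databases and in NCBI dumps
.rank_alias <- c(
  superkingdom = "SuperKingdom", domain = "SuperKingdom", realm = "SuperKingdom",
  kingdom = "Kingdom", phylum = "Phylum", division = "Phylum",
  class = "Class", order = "Order", family = "Family",
  genus = "Genus", species = "Species"
)

.normalize_rank_name <- function(rank) {
  out <- .rank_alias[tolower(trimws(rank))]
  unname(out)
}

#' Build a taxonomy reference
#'
#' An in-memory reference in the shape of the NCBI taxonomy dump: a node
#' table (id, parent id, rank) and a name table (id, canonical name).
#' Parent links must be acyclic with a single root (a node that is its
#' own parent, as in the NCBI dump) and every node needs a name.
#'
#' @param nodes Data frame with columns `id`, `parent`, `rank`.
#' @param names Data frame with columns `id`, `name`.
#' @return A list of class `taxonomy_reference`.
#' @seealso [read_taxdump()], [make_fixture_taxonomy()]
#' @export
taxonomy_reference <- function(nodes, names) {
  nodes <- tibble::as_tibble(nodes)
  names <- tibble::as_tibble(names)
  stopifnot(all(c("id", "parent", "rank") %in% base::names(nodes)),
            all(c("id", "name") %in% base::names(names)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  root <- nodes$id[nodes$id == nodes$parent]
  if (length(root) != 1) {
    stop("reference must have exactly one root (id == parent)", call. = FALSE)
  }
  if (!all(nodes$parent %in% nodes$id)) {
    stop("dangling parent links in node table", call. = FALSE)
  }
  missing_names <- setdiff(nodes$id, as.integer(names$id))
  if (length(missing_names) > 0) {
    stop("every node id needs at least one name", call. = FALSE)
  }
  # acyclicity: walking parents from every node must reach the root
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- integer()
    cur <- id
    while (cur != root) {
      if (cur %in% seen) stop("cycle in parent links", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  structure(list(nodes = nodes, names = names, root = root),
            class = "taxonomy_reference")
}

#' @export
print.taxonomy_reference <- function(x, ...) {
  cat(sprintf("<taxonomy_reference> %d nodes, %d names\n",
              nrow(x$nodes), nrow(x$names)))
  invisible(x)
}

#' Read an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp` and `names.dmp` in the pipe-delimited NCBI dump
#' format (`id\t|\tparent\t|\trank\t|...`). Only rows of name class
#' `scientific name` are kept from the name table (all rows are kept
#' when the file has no class column).
#'
#' @param dir Directory holding `nodes.dmp` and `names.dmp`; or pass the
#'   two file paths explicitly.
#' @param nodes_file,names_file Optional explicit paths.
#' @return A [taxonomy_reference()].
#' @export
read_taxdump <- function(dir = NULL, nodes_file = NULL, names_file = NULL) {
  if (!is.null(dir)) {
    nodes_file <- file.path(dir, "nodes.dmp")
    names_file <- file.path(dir, "names.dmp")
  }
  parse_dmp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    fields
  }
  nd <- parse_dmp(nodes_file)
  nodes <- tibble::tibble(
    id = as.integer(purrr::map_chr(nd, 1)),
    parent = as.integer(purrr::map_chr(nd, 2)),
    rank = trimws(purrr::map_chr(nd, 3))
  )
  nm <- parse_dmp(names_file)
  names_tbl <- tibble::tibble(
    id = as.integer(purrr::map_chr(nm, 1)),
    name = trimws(purrr::map_chr(nm, 2)),
    class = purrr::map_chr(nm, ~ if (length(.x) >= 4) trimws(.x[[4]]) else "")
  )
  has_class <- any(nzchar(names_tbl$class))
  if (has_class) {
    names_tbl <- names_tbl[names_tbl$class == "scientific name", ]
  }
  taxonomy_reference(nodes, names_tbl[c("id", "name")])
}

#' Write a taxonomy reference as an NCBI-style dump
#'
#' @param ref A [taxonomy_reference()].
#' @param dir Output directory; `nodes.dmp` and `names.dmp` are created.
#' @return `dir`, invisibly.
#' @export
write_taxdump <- function(ref, dir) {
  stopifnot(inherits(ref, "taxonomy_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", ref$nodes$id, ref$nodes$parent,
                     ref$nodes$rank), file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     ref$names$id, ref$names$name),
             file.path(dir, "names.dmp"))
  invisible(dir)
}

# lineage walk from a node to the root, returning rank -> name for the
# eight harmonized ranks found along the way
.reference_lineage <- function(ref, id) {
  parent_of <- stats::setNames(ref$nodes$parent, ref$nodes$id)
  rank_of <- stats::setNames(ref$nodes$rank, ref$nodes$id)
  name_of <- stats::setNames(ref$names$name, ref$names$id)
  slots <- stats::setNames(rep("", 8), taxonomy_ranks())
  cur <- id
  repeat {
    rk <- .normalize_rank_name(rank_of[[as.character(cur)]])
    if (!is.na(rk) && slots[[rk]] == "") {
      slots[[rk]] <- unname(name_of[[as.character(cur)]])
    }
    nxt <- parent_of[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  slots
}

#' Normalize a partial taxonomic lineage to the eight fixed ranks
#'
#' The deepest provided name is looked up in the reference by exact,
#' case-insensitive name match (falling back to the next-deepest name on
#' failure). On a match the full lineage is reconstructed by walking the
#' reference tree to the root, filling all eight ranks the reference
#' knows; provided names at ranks the reference lacks are kept. Without
#' any match the provided names are simply placed into their slots and
#' the other levels remain blank.
#'
#' @param lineage Named character vector or list, rank name to taxon
#'   name. Rank names are case-insensitive and common synonyms
#'   (`domain` for SuperKingdom, `division` for Phylum) are accepted.
#'   At least one non-blank name is required.
#' @param ref A [taxonomy_reference()], or `NULL` to skip matching.
#' @return A one-row tibble with the eight rank columns (blank = `""`)
#'   and a `provenance` column, `"ncbi_matched"` or
#'   `"preserved_original"`.
#' @examples
#' normalize_taxonomy(c(Genus = "Coffea", Species = "Coffea arabica"),
#'                    ref = make_fixture_taxonomy(fixture_spec(seed = 1)))
#' @export
normalize_taxonomy <- function(lineage, ref = NULL) {
  lineage <- unlist(lineage)
  if (length(lineage) == 0 || is.null(names(lineage))) {
    stop("lineage must be a named rank -> name mapping", call. = FALSE)
  }
  ranks <- .normalize_rank_name(names(lineage))
  keep <- !is.na(ranks) & !is.na(lineage) & nzchar(trimws(lineage))
  lineage <- trimws(lineage[keep])
  ranks <- ranks[keep]
  if (length(lineage) == 0) {
    stop("lineage has no recognizable named rank", call. = FALSE)
  }
  slots <- stats::setNames(rep("", 8), taxonomy_ranks())
  slots[ranks] <- lineage
  provenance <- "preserved_original"

  if (!is.null(ref)) {
    depth_order <- order(match(ranks, taxonomy_ranks()), decreasing = TRUE)
    lname <- tolower(ref$names$name)
    rank_of <- stats::setNames(ref$nodes$rank, ref$nodes$id)
    for (k in depth_order) {
      hit <- which(lname == tolower(lineage[[k]]))
      if (length(hit) == 0) next
      ids <- ref$names$id[hit]
      # prefer a node whose reference rank agrees with the provided one
      agree <- ids[.normalize_rank_name(rank_of[as.character(ids)]) %in%
                     ranks[[k]]]
      id <- if (length(agree) > 0) agree[[1]] else ids[[1]]
      walked <- .reference_lineage(ref, id)
      filled <- walked != ""
      slots[filled] <- walked[filled]
      provenance <- "ncbi_matched"
      break
    }
  }
  out <- tibble::as_tibble(as.list(slots))
  out$provenance <- provenance
  out
}
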
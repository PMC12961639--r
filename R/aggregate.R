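#' Construct a compound store
#'
#' A store is the local aggregated compound database: one row (document)
#' per unique stereo/tautomer-insensitive structure key, sorted by
#' monoisotopic mass so that mass searches can binary-search the window.
#'
#' @param documents Tibble of merged documents as produced by
#'   [aggregate_records()]; required columns `key`, `structure`,
#'   `formula`, `monoisotopic_mass`, `formal_charge`, plus list-columns
#'   `sources`, `labels`, `activities`, `taxonomies`, `references`.
#' @return A tibble of class `compound_store` sorted by mass, then key.
#' @export
compound_store <- function(documents) {
  documents <- tibble::as_tibble(documents)
  need <- c("key", "structure", "formula", "monoisotopic_mass",
            "formal_charge", "sources", "labels", "activities",
            "taxonomies", "references")
  missing <- setdiff(need, names(documents))
  if (length(missing) > 0) {
    stop("store is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(documents$key)) {
    stop("duplicate structure keys in store", call. = FALSE)
  }
  documents <- documents[order(documents$monoisotopic_mass, documents$key), ,
                         drop = FALSE]
  class(documents) <- c("compound_store", class(tibble::tibble()))
  documents
}

#' @export
print.compound_store <- function(x, ...) {
  cat(sprintf("<compound_store> %d documents\n", nrow(x)))
  NextMethod()
}

# one normalized per-source record row from a raw input record (a list)
.normalize_record <- function(rec) {
  structure_ <- rec$structure %||% NA_character_
  acts <- rec$activities %||% list()
  if (is.data.frame(acts)) acts <- purrr::transpose(acts)
  taxa <- rec$taxonomies %||% list()
  if (!is.null(names(taxa)) && length(names(taxa)) > 0 &&
      all(nzchar(names(taxa)))) {
    taxa <- list(taxa)  # a single lineage given as a flat named map
  }
  tibble::tibble(
    structure = as.character(structure_),
    source = as.character(rec$source %||% NA_character_),
    source_id = as.character(rec$source_id %||% NA_character_),
    name = as.character(rec$name %||% NA_character_),
    activities = list(acts),
    taxonomies = list(taxa),
    references = list(sort(unique(as.character(unlist(
      rec$references %||% character()
    )))))
  )
}

#' Merge per-source records sharing one structure key into one document
#'
#' Source entries are concatenated and deduplicated by (source, source
#' id); activities, taxonomies, labels and literature references are
#' set-unioned with a canonical sort, so the merge is associative and
#' invariant under input order. All rows must carry the same key.
#'
#' @param rows Tibble of normalized per-source rows (one key).
#' @return A one-row tibble (document).
#' @keywords internal
merge_records <- function(rows) {
  key <- unique(rows$key)
  if (length(key) != 1) {
    stop("merge_records: records do not share a single key", call. = FALSE)
  }
  sources <- tibble::tibble(
    source = rows$source, source_id = rows$source_id,
    raw_structure = rows$structure
  )
  sources <- sources[!duplicated(sources[c("source", "source_id")]), ]
  sources <- sources[order(sources$source, sources$source_id), ]

  acts <- unlist(rows$activities, recursive = FALSE)
  acts <- unique(purrr::map(acts, ~ .x[order(names(.x))]))
  acts <- acts[order(purrr::map_chr(acts, ~ paste(unlist(.x), collapse = "|")))]

  taxa <- unlist(rows$taxonomies, recursive = FALSE)
  taxa <- unique(purrr::map(taxa, ~ .x[order(names(.x))]))
  taxa <- taxa[order(purrr::map_chr(taxa, ~ paste(unlist(.x), collapse = "|")))]

  refs <- sort(unique(unlist(rows$references)))

  labels <- sort(unique(unlist(rows$labels)))

  tibble::tibble(
    key = key,
    structure = rows$canonical_structure[[1]],
    formula = rows$formula[[1]],
    monoisotopic_mass = rows$monoisotopic_mass[[1]],
    formal_charge = rows$formal_charge[[1]],
    sources = list(sources),
    labels = list(labels),
    activities = list(acts),
    taxonomies = list(taxa),
    references = list(refs)
  )
}

#' Aggregate multi-source compound records into a compound store
#'
#' The full aggregation pass: each record's structure is canonicalized
#' to its stereo/tautomer-insensitive key, records are grouped by key
#' and merged into unified documents, taxonomies are normalized to the
#' eight fixed ranks against the reference, and labels are attached —
#' `natural-product` when any contributing source is on the
#' natural-product source list, `bioactive` when any linked activity has
#' a positive outcome. Records whose structure cannot be parsed (or is a
#' salt/mixture) are skipped with a warning and counted, never fatal.
#'
#' @param records A list of record lists, or a tibble with columns
#'   `structure`, `source`, `source_id` and optional `name`,
#'   `activities` (list of `list(assay=, active=)`), `taxonomies`
#'   (list of named rank to name maps), `references`.
#' @param tax_ref Optional [taxonomy_reference()] for lineage
#'   normalization.
#' @param np_sources Character vector of source names recognized as
#'   natural-product databases.
#' @return A [compound_store()]; attribute `skipped` holds the number of
#'   records dropped.
#' @export
aggregate_records <- function(records, tax_ref = NULL,
                              np_sources = character()) {
  if (is.data.frame(records)) {
    df <- tibble::as_tibble(records)
    records <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      lapply(r, function(x) if (is.list(x) && length(x) == 1) x[[1]] else x)
    })
  }
  if (length(records) == 0) {
    out <- compound_store(.empty_documents())
    attr(out, "skipped") <- 0L
    return(out)
  }
  rows <- dplyr::bind_rows(purrr::map(records, .normalize_record))

  keys <- suppressWarnings(no_stereo_tautomer_id(rows$structure))
  skipped <- sum(is.na(keys))
  if (skipped > 0) {
    warning(sprintf("aggregate_records: skipped %d record(s) with invalid structures",
                    skipped), call. = FALSE)
  }
  rows$key <- keys
  rows <- rows[!is.na(keys), , drop = FALSE]
  if (nrow(rows) == 0) {
    out <- compound_store(.empty_documents())
    attr(out, "skipped") <- skipped
    return(out)
  }

  # per-key chemistry, computed once per unique key
  uk <- unique(rows$key)
  chem <- tibble::tibble(
    key = uk,
    canonical_structure = key_to_smiles(uk),
    formula = .inchi_formula(uk),
    formal_charge = .inchi_charge(uk)
  )
  chem$monoisotopic_mass <- purrr::map_dbl(chem$formula, function(f) {
    if (is.na(f)) return(NA_real_)
    tryCatch(monoisotopic_mass(parse_formula(f)), error = function(e) NA_real_)
  })
  rows <- dplyr::left_join(rows, chem, by = "key")

  # labels from source membership and activity outcomes
  rows$labels <- purrr::map2(rows$source, rows$activities, function(src, acts) {
    lab <- character()
    if (!is.na(src) && src %in% np_sources) lab <- c(lab, "natural-product")
    if (any(purrr::map_lgl(acts, ~ isTRUE(.x$active)))) {
      lab <- c(lab, "bioactive")
    }
    lab
  })

  docs <- rows |>
    dplyr::group_by(.data$key) |>
    dplyr::group_split() |>
    purrr::map(merge_records) |>
    dplyr::bind_rows()

  if (!is.null(tax_ref)) {
    docs$taxonomies <- purrr::map(docs$taxonomies, function(taxa) {
      norm <- purrr::map(taxa, function(lin) {
        tryCatch(normalize_taxonomy(lin, tax_ref),
                 error = function(e) NULL)
      })
      out <- dplyr::bind_rows(purrr::compact(norm))
      if (nrow(out) > 0) {
        out <- dplyr::distinct(out)
        out <- out[do.call(order, as.list(out)), , drop = FALSE]
      }
      out
    })
  }

  out <- compound_store(docs)
  attr(out, "skipped") <- skipped
  out
}

.empty_documents <- function() {
  tibble::tibble(
    key = character(), structure = character(), formula = character(),
    monoisotopic_mass = double(), formal_charge = integer(),
    sources = list(), labels = list(), activities = list(),
    taxonomies = list(), references = list()
  )
}

#' Search a compound store by neutral monoisotopic mass
#'
#' Returns all documents whose stored monoisotopic mass lies within
#' `tol_ppm` of the query mass. The store is sorted by mass, so the
#' window is located by binary search rather than a full scan.
#'
#' @param store A [compound_store()].
#' @param mass Query neutral monoisotopic mass in Da.
#' @param tol_ppm Tolerance in ppm (> 0).
#' @return The matching documents, a tibble.
#' @export
search_by_mass <- function(store, mass, tol_ppm = 5) {
  stopifnot(is.numeric(mass), length(mass) == 1, tol_ppm > 0)
  m <- store$monoisotopic_mass
  lo <- mass * (1 - tol_ppm * 1e-6)
  hi <- mass * (1 + tol_ppm * 1e-6)
  i0 <- findInterval(lo, m, left.open = TRUE) + 1L
  i1 <- findInterval(hi, m)
  if (i0 > i1) return(tibble::as_tibble(store)[0, , drop = FALSE])
  tibble::as_tibble(store)[i0:i1, , drop = FALSE]
}

#' Keep formula candidates with known neutral structures in a store
#'
#' Mirrors the screening step that keeps only candidate formulas backed
#' by at least `min_structures` structures in a compound database,
#' counting only neutral molecules (formal charge zero). Surviving
#' candidates get `has_known_structures = TRUE`, and
#' `bioactive_or_natural = TRUE` when any backing document carries a
#' `bioactive` or `natural-product` label. Relative candidate order is
#' preserved.
#'
#' @param cands Candidate tibble from [enumerate_formulas()].
#' @param store A [compound_store()].
#' @param min_structures Minimum number of neutral backing structures.
#' @return The filtered candidate tibble, a subset of the input rows.
#' @export
filter_known_structures <- function(cands, store, min_structures = 5) {
  stopifnot(min_structures >= 1)
  if (nrow(cands) == 0 || nrow(store) == 0) {
    return(cands[0, , drop = FALSE])
  }
  neutral <- tibble::as_tibble(store)
  neutral <- neutral[!is.na(neutral$formal_charge) &
                       neutral$formal_charge == 0L, , drop = FALSE]
  counts <- table(neutral$formula)
  n_known <- as.integer(counts[cands$formula])
  n_known[is.na(n_known)] <- 0L
  keep <- n_known >= min_structures
  out <- cands[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  out$has_known_structures <- TRUE
  out$bioactive_or_natural <- purrr::map_lgl(out$formula, function(fm) {
    labs <- unlist(neutral$labels[neutral$formula == fm])
    any(labs %in% c("bioactive", "natural-product"))
  })
  out
}
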
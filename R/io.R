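#' Read centroided spectra from MGF, MSP or JSON files
#'
#' Supported dialects: MGF (`BEGIN IONS`/`END IONS` blocks with
#' `TITLE`, `PEPMASS`, `CHARGE` headers), MSP (`Name:` /
#' `PrecursorMZ:` / `Num Peaks:` stanzas) and the package's JSON
#' spectrum schema (an array of objects with `peaks` as an array of
#' `[mz, intensity]` pairs plus optional `title`, `precursor_mz`,
#' `adduct`, `formula`, `source`). Malformed entries are reported with
#' their line numbers and skipped: a partially valid file yields the
#' valid spectra plus a `warnings` attribute listing what was dropped.
#'
#' @param path File path.
#' @param format `"mgf"`, `"msp"` or `"json"`; guessed from the file
#'   extension by default.
#' @return A list of [spectrum()] objects; attribute `warnings` is a
#'   character vector of skip messages (empty when the file was clean).
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mgf = "mgf", msp = "msp", json = "json",
                     stop("cannot guess spectrum format from '", path, "'",
                          call. = FALSE))
  }
  switch(format,
         mgf = .read_mgf(path),
         msp = .read_msp(path),
         json = .read_spectra_json(path))
}

.with_warnings <- function(spectra, warnings) {
  attr(spectra, "warnings") <- warnings
  spectra
}

.parse_peak_lines <- function(lines) {
  parts <- strsplit(trimws(lines), "[ \t]+")
  mz <- suppressWarnings(as.numeric(purrr::map_chr(parts, 1)))
  int <- suppressWarnings(as.numeric(purrr::map_chr(
    parts, ~ if (length(.x) >= 2) .x[[2]] else NA_character_
  )))
  list(mz = mz, intensity = int,
       ok = !is.na(mz) & !is.na(int) & int >= 0 & mz > 0)
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  spectra <- list()
  warns <- character()
  for (b in begins) {
    e <- ends[ends > b][1]
    if (is.na(e)) {
      warns <- c(warns, sprintf("line %d: BEGIN IONS without END IONS", b))
      next
    }
    block <- lines[(b + 1):(e - 1)]
    is_hdr <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
    hdr <- block[is_hdr]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    meta <- stats::setNames(as.list(vals), keys)
    pk_lines <- block[!is_hdr & nzchar(trimws(block))]
    pk <- .parse_peak_lines(pk_lines)
    if (any(!pk$ok)) {
      bad_at <- b + which(!is_hdr & nzchar(trimws(block)))[!pk$ok]
      warns <- c(warns, sprintf("line %d: unparseable peak, entry at line %d skipped",
                                bad_at[[1]], b))
      next
    }
    if (length(pk$mz) == 0) {
      warns <- c(warns, sprintf("line %d: entry has no peaks, skipped", b))
      next
    }
    pmz <- if (!is.null(meta$PEPMASS)) {
      suppressWarnings(as.numeric(strsplit(trimws(meta$PEPMASS), "[ \t]+")[[1]][1]))
    } else NULL
    if (!is.null(pmz) && is.na(pmz)) pmz <- NULL
    md <- list(title = meta$TITLE, activation = meta$ACTIVATION,
               source_id = meta$SOURCE_ID, charge = meta$CHARGE)
    md <- md[!purrr::map_lgl(md, is.null)]
    spectra[[length(spectra) + 1]] <- spectrum(
      pk$mz, pk$intensity, precursor_mz = pmz,
      precursor_adduct = meta$ADDUCT, metadata = md
    )
  }
  .with_warnings(spectra, warns)
}

.read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name_at <- grep("^\\s*Name\\s*:", lines, ignore.case = TRUE)
  bounds <- c(name_at, length(lines) + 1L)
  spectra <- list()
  warns <- character()
  for (k in seq_along(name_at)) {
    b <- name_at[k]; e <- bounds[k + 1] - 1L
    block <- lines[b:e]
    is_hdr <- grepl("^\\s*[A-Za-z][A-Za-z0-9_ ]*:", block)
    hdr <- block[is_hdr]
    keys <- toupper(gsub(" ", "", sub(":.*$", "", hdr)))
    vals <- trimws(sub("^[^:]*:", "", hdr))
    meta <- stats::setNames(as.list(vals), keys)
    pk_lines <- block[!is_hdr & nzchar(trimws(block))]
    pk <- .parse_peak_lines(pk_lines)
    if (length(pk$mz) == 0 || any(!pk$ok)) {
      warns <- c(warns, sprintf("line %d: entry '%s' has no valid peak list, skipped",
                                b, meta$NAME %||% "?"))
      next
    }
    n_declared <- suppressWarnings(as.integer(meta$NUMPEAKS %||% NA))
    if (!is.na(n_declared) && n_declared != length(pk$mz)) {
      warns <- c(warns, sprintf(
        "line %d: entry '%s' declares %d peaks but has %d, skipped",
        b, meta$NAME %||% "?", n_declared, length(pk$mz)))
      next
    }
    pmz <- suppressWarnings(as.numeric(meta$PRECURSORMZ %||% NA))
    md <- list(title = meta$NAME, formula = meta$FORMULA,
               activation = meta$ACTIVATION, source_id = meta$DB)
    md <- md[!purrr::map_lgl(md, is.null)]
    spectra[[length(spectra) + 1]] <- spectrum(
      pk$mz, pk$intensity,
      precursor_mz = if (!is.na(pmz)) pmz else NULL,
      precursor_adduct = meta$PRECURSORTYPE, metadata = md
    )
  }
  .with_warnings(spectra, warns)
}

.read_spectra_json <- function(path) {
  raw <- jsonlite::read_json(path)
  spectra <- list()
  warns <- character()
  for (k in seq_along(raw)) {
    entry <- raw[[k]]
    pk <- entry$peaks
    res <- tryCatch({
      mz <- purrr::map_dbl(pk, ~ as.numeric(.x[[1]]))
      int <- purrr::map_dbl(pk, ~ as.numeric(.x[[2]]))
      md <- entry[setdiff(names(entry), c("peaks", "precursor_mz", "adduct"))]
      spectrum(mz, int,
               precursor_mz = entry$precursor_mz,
               precursor_adduct = entry$adduct, metadata = md)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warns <- c(warns, sprintf("entry %d: %s, skipped", k, res))
    } else {
      spectra[[length(spectra) + 1]] <- res
    }
  }
  .with_warnings(spectra, warns)
}

#' Write spectra to MGF, MSP or JSON
#'
#' Inverse of [read_spectra()]: everything a writer produces, the
#' corresponding reader accepts, and peaks round-trip within float
#' printing precision.
#'
#' @param spectra A list of [spectrum()] objects (or a single spectrum).
#' @param path Output path.
#' @param format `"mgf"`, `"msp"` or `"json"`; guessed from extension.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path,
                          format = c("auto", "mgf", "msp", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mgf = "mgf", msp = "msp", json = "json",
                     stop("cannot guess spectrum format from '", path, "'",
                          call. = FALSE))
  }
  if (is.data.frame(spectra)) spectra <- list(spectra)
  num <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  lines <- character()
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    md <- attr(s, "metadata") %||% list()
    title <- md$title %||% sprintf("spectrum_%d", k)
    pmz <- precursor_mz(s)
    if (format == "mgf") {
      lines <- c(lines, "BEGIN IONS", paste0("TITLE=", title))
      if (!is.null(pmz)) lines <- c(lines, paste0("PEPMASS=", num(pmz)))
      ad <- attr(s, "precursor_adduct")
      if (!is.null(ad)) lines <- c(lines, paste0("ADDUCT=", ad))
      if (!is.null(md$activation)) {
        lines <- c(lines, paste0("ACTIVATION=", md$activation))
      }
      lines <- c(lines, paste(num(s$mz), num(s$intensity)), "END IONS", "")
    } else if (format == "msp") {
      lines <- c(lines, paste0("Name: ", title))
      if (!is.null(pmz)) lines <- c(lines, paste0("PrecursorMZ: ", num(pmz)))
      ad <- attr(s, "precursor_adduct")
      if (!is.null(ad)) lines <- c(lines, paste0("PrecursorType: ", ad))
      if (!is.null(md$formula)) lines <- c(lines, paste0("Formula: ", md$formula))
      lines <- c(lines, paste0("Num Peaks: ", nrow(s)),
                 paste(num(s$mz), num(s$intensity)), "")
    }
  }
  if (format == "json") {
    payload <- purrr::map(seq_along(spectra), function(k) {
      s <- spectra[[k]]
      md <- attr(s, "metadata") %||% list()
      out <- c(
        list(peaks = purrr::map2(s$mz, s$intensity, ~ c(.x, .y))),
        if (!is.null(precursor_mz(s))) list(precursor_mz = precursor_mz(s)),
        if (!is.null(attr(s, "precursor_adduct"))) {
          list(adduct = attr(s, "precursor_adduct"))
        },
        md
      )
      out
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Export a result table as JSON or tab-delimited text
#'
#' JSON export round-trips losslessly through [import_results()]. The
#' tab-delimited form has one header row and one row per result;
#' ppm errors and similarity scores are printed to 2 decimals, other
#' numbers in full; list-columns are collapsed with `;`.
#'
#' @param results A data frame (e.g. candidates, search hits).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`; guessed from extension.
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", tsv = "tsv", txt = "tsv",
                     stop("cannot guess export format from '", path, "'",
                          call. = FALSE))
  }
  results <- tibble::as_tibble(results)
  if (format == "json") {
    plain <- results
    plain$counts <- NULL  # formula text is the canonical serialized form
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    out <- results
    out$counts <- NULL
    two_dp <- intersect(names(out), c("ppm_error", "score",
                                      "isotopic_similarity",
                                      "percent_assigned"))
    for (col in two_dp) out[[col]] <- sprintf("%.2f", out[[col]])
    for (col in names(out)) {
      if (is.list(out[[col]])) {
        out[[col]] <- purrr::map_chr(out[[col]], function(x) {
          paste(unlist(x), collapse = ";")
        })
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_results
#' @return `import_results()`: the table as a tibble.
#' @export
import_results <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Read and write per-source compound record dumps
#'
#' Record dumps are line-delimited JSON: one record object per line with
#' fields `structure`, `source`, `source_id` and optional `name`,
#' `activities`, `taxonomies`, `references` (see [aggregate_records()]).
#'
#' @param path File path.
#' @return `read_records()`: a list of record lists.
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map(lines, jsonlite::fromJSON, simplifyVector = FALSE)
}

#' @rdname read_records
#' @param records A list of record lists.
#' @export
write_records <- function(records, path) {
  lines <- purrr::map_chr(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Serialize and restore a compound store as JSON
#'
#' @param store A [compound_store()].
#' @param path File path.
#' @return `write_store()`: `path` invisibly; `read_store()`: the store.
#' @export
write_store <- function(store, path) {
  docs <- purrr::map(seq_len(nrow(store)), function(i) {
    list(
      key = store$key[[i]],
      structure = store$structure[[i]],
      formula = store$formula[[i]],
      monoisotopic_mass = store$monoisotopic_mass[[i]],
      formal_charge = store$formal_charge[[i]],
      sources = store$sources[[i]],
      labels = as.list(store$labels[[i]]),
      activities = store$activities[[i]],
      taxonomies = store$taxonomies[[i]],
      references = as.list(store$references[[i]])
    )
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  docs <- jsonlite::read_json(path)
  if (length(docs) == 0) return(compound_store(.empty_documents()))
  tab <- tibble::tibble(
    key = purrr::map_chr(docs, "key"),
    structure = purrr::map_chr(docs, ~ .x$structure %||% NA_character_),
    formula = purrr::map_chr(docs, ~ .x$formula %||% NA_character_),
    monoisotopic_mass = purrr::map_dbl(docs, ~ .x$monoisotopic_mass %||% NA_real_),
    formal_charge = purrr::map_int(docs, ~ as.integer(.x$formal_charge %||% NA)),
    sources = purrr::map(docs, function(d) {
      dplyr::bind_rows(purrr::map(d$sources, tibble::as_tibble))
    }),
    labels = purrr::map(docs, ~ as.character(unlist(.x$labels))),
    activities = purrr::map(docs, "activities"),
    taxonomies = purrr::map(docs, function(d) {
      dplyr::bind_rows(purrr::map(d$taxonomies, tibble::as_tibble))
    }),
    references = purrr::map(docs, ~ as.character(unlist(.x$references)))
  )
  compound_store(tab)
}

#' Read a package configuration file
#'
#' YAML key-value configuration with two recognized sections:
#' `adducts`, a list of `{name, delta: {element: count}, charge}`
#' entries added to the registry, and `element_ranges`, named
#' range-preset strings (see [element_ranges()]).
#'
#' @param path Path to a YAML file.
#' @return A list with `adducts` (tibble in [adduct_registry()] shape,
#'   possibly empty) and `element_ranges` (named list of
#'   `element_ranges` objects).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  adducts <- tibble::tibble(name = character(), charge = integer(),
                            delta = list())
  if (!is.null(cfg$adducts)) {
    adducts <- dplyr::bind_rows(purrr::map(cfg$adducts, function(a) {
      tibble::tibble(
        name = a$name,
        charge = as.integer(a$charge),
        delta = list(stats::setNames(as.integer(unlist(a$delta)),
                                     names(a$delta)))
      )
    }))
  }
  presets <- purrr::map(cfg$element_ranges %||% list(), element_ranges)
  list(adducts = adducts, element_ranges = presets)
}
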
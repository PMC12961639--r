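# Structure canonicalization via the Open Babel command-line tool.
# Only the aggregation functions need it; everything mass-spectral works
# without a structure backend.

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("the 'obabel' executable is required for structure ",
         "canonicalization but was not found on PATH", call. = FALSE)
  }
  unname(p)
}

# Batch conversion keyed by an index title so that entries Open Babel
# cannot parse come back as NA instead of silently shifting the output.
# The InChI reader does not tolerate inline titles, so InChI input runs
# untitled; if any entry fails (line counts disagree) it falls back to
# one call per entry to keep the alignment.
.obabel_convert <- function(inputs, in_format, out_args) {
  infile <- tempfile(fileext = paste0(".", in_format))
  on.exit(unlink(infile), add = TRUE)
  titled <- in_format != "inchi"
  run <- function(lines, args) {
    writeLines(lines, infile)
    suppressWarnings(system2(.obabel_path(), c(infile, args, "-e"),
                             stdout = TRUE, stderr = FALSE))
  }
  res <- rep(NA_character_, length(inputs))
  if (titled) {
    idx <- seq_along(inputs)
    out <- run(paste(inputs, paste0("msd", idx)), c(out_args, "-xt"))
    m <- stringr::str_match(out, "^(.*\\S)\\s+msd([0-9]+)$")
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    if (nrow(m) > 0) res[as.integer(m[, 3])] <- m[, 2]
  } else {
    out <- trimws(run(inputs, out_args))
    out <- out[nzchar(out)]
    if (length(out) == length(inputs)) {
      res <- out
    } else {
      for (i in seq_along(inputs)) {
        oi <- trimws(run(inputs[[i]], out_args))
        oi <- oi[nzchar(oi)]
        if (length(oi) == 1) res[[i]] <- oi
      }
    }
  }
  res
}

#' Stereochemistry- and tautomer-insensitive structure key
#'
#' Computes, for each structure, a deterministic key that is identical
#' for all stereoisomers of a compound and for tautomers related by the
#' standard InChI mobile-hydrogen treatment: the key is the standard
#' InChI of the structure with the stereochemical layers truncated.
#' Compounds drawn with different or missing stereo descriptors, or in
#' different mobile-H tautomeric forms, therefore collapse to one key
#' and can be merged into a single record. This is an approximation:
#' tautomerism beyond the standard InChI rules (e.g. keto-enol shifts
#' over carbon) is not collapsed.
#'
#' Multi-component structures (salts, mixtures; SMILES containing `.`)
#' and structures Open Babel cannot parse yield `NA` with a warning
#' rather than an error, so long-running aggregation jobs keep going.
#'
#' @param structures Character vector of SMILES strings.
#' @return Character vector of keys (`NA` where the structure was
#'   rejected or unparseable).
#' @examples
#' \dontrun{
#' no_stereo_tautomer_id(c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O"))
#' }
#' @export
no_stereo_tautomer_id <- function(structures) {
  stopifnot(is.character(structures))
  res <- rep(NA_character_, length(structures))
  ok <- !is.na(structures) & nzchar(structures) &
    !grepl(".", structures, fixed = TRUE)
  multi <- sum(!is.na(structures) & grepl(".", structures, fixed = TRUE))
  if (multi > 0) {
    warning(sprintf("%d multi-component structure(s) (salts/mixtures) skipped",
                    multi), call. = FALSE)
  }
  if (any(ok)) {
    res[ok] <- .obabel_convert(structures[ok], "smi",
                               c("-oinchi", "-xT", "nostereo", "-xw"))
  }
  failed <- sum(ok & is.na(res))
  if (failed > 0) {
    warning(sprintf("%d structure(s) could not be parsed and were skipped",
                    failed), call. = FALSE)
  }
  res
}

#' Canonical stereo-stripped SMILES for a structure key
#'
#' Renders the display form of a [no_stereo_tautomer_id()] key as a
#' canonical SMILES (stereochemistry absent by construction).
#'
#' @param keys Character vector of keys (truncated standard InChIs).
#' @return Canonical SMILES strings (`NA` where conversion failed).
#' @export
key_to_smiles <- function(keys) {
  res <- rep(NA_character_, length(keys))
  ok <- !is.na(keys) & nzchar(keys)
  if (any(ok)) res[ok] <- .obabel_convert(keys[ok], "inchi", "-ocan")
  res
}

# formula layer of an InChI: second '/'-separated field
.inchi_formula <- function(inchi) {
  out <- rep(NA_character_, length(inchi))
  ok <- !is.na(inchi) & startsWith(inchi, "InChI=")
  parts <- strsplit(inchi[ok], "/", fixed = TRUE)
  out[ok] <- purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else
    NA_character_)
  out
}

# net formal charge: /q layer plus /p layer (added/removed protons)
.inchi_charge <- function(inchi) {
  layer_val <- function(x, tag) {
    m <- stringr::str_match(x, paste0("/", tag, "([+-][0-9]+)"))[, 2]
    v <- suppressWarnings(as.integer(m))
    ifelse(is.na(v), 0L, v)
  }
  ifelse(is.na(inchi), NA_integer_,
         layer_val(inchi, "q") + layer_val(inchi, "p"))
}
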
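#' Parse a molecular formula string
#'
#' Turns a plain formula string such as `"C11H15NO2"` into a named integer
#' vector of element counts. Counts default to 1 when omitted
#' (`"NO2"` is N1 O2). Zero-count elements are dropped so the
#' representation is canonical: two formulas are equal iff their count
#' vectors are identical.
#'
#' @param text A single formula string. Element symbols must be known to
#'   [element_table()]; counts must be positive integers.
#' @return A named integer vector of element counts (class `mol_formula`).
#' @examples
#' parse_formula("C11H15NO2")
#' parse_formula("H2O")
#' @seealso [formula_string()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(text)) {
    stop("formula text must be a single non-empty string", call. = FALSE)
  }
  tokens <- stringr::str_match_all(
    text, "([A-Z][a-z]?)([0-9]*)|(.)"
  )[[1]]
  bad <- tokens[, 4]
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0) {
    stop(sprintf("malformed formula '%s': unexpected token '%s'",
                 text, bad[[1]]), call. = FALSE)
  }
  symbols <- tokens[, 2]
  counts <- tokens[, 3]
  .check_elements(symbols, context = sprintf("'%s'", text))
  n <- ifelse(counts == "", 1L, suppressWarnings(as.integer(counts)))
  if (anyNA(n) || any(n <= 0)) {
    stop(sprintf("malformed count in formula '%s'", text), call. = FALSE)
  }
  counts <- tapply(n, symbols, sum)
  mol_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector or list, element symbol to count.
#'   Negative counts are rejected; zero counts are dropped.
#' @return A named integer vector of class `mol_formula`.
#' @examples
#' mol_formula(c(C = 11, H = 15, N = 1, O = 2))
#' @export
mol_formula <- function(counts = integer()) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    out <- stats::setNames(integer(), character())
    class(out) <- "mol_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be named by element symbol", call. = FALSE)
  }
  .check_elements(names(counts))
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  out <- counts[.hill_order(names(counts))]
  class(out) <- "mol_formula"
  out
}

# Hill convention: C first, then H, then all other elements alphabetically.
# Without carbon, everything (H included) is alphabetical.
.hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

#' Canonical text form of a formula (Hill order)
#'
#' @param f A `mol_formula` or named count vector.
#' @return A single string, e.g. `"C11H15NO2"`; `""` for the empty formula.
#' @examples
#' formula_string(parse_formula("O2NC11H15"))  # "C11H15NO2"
#' @export
formula_string <- function(f) {
  f <- as_mol_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
format.mol_formula <- function(x, ...) formula_string(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", formula_string(x), "  (",
      format(monoisotopic_mass(x), nsmall = 5), " Da)\n", sep = "")
  invisible(x)
}

#' Coerce to a molecular formula
#'
#' @param x A `mol_formula`, a named count vector, or a formula string.
#' @return A `mol_formula`.
#' @export
as_mol_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  mol_formula(x)
}

#' Element-wise formula arithmetic
#'
#' `formula_add()` merges two compositions; `formula_subtract()` removes
#' atoms and errors if the result would have a negative count (the caller
#' is asking to remove atoms the formula does not have).
#'
#' @param f,g Formulas (any form accepted by [as_mol_formula()]), except
#'   that `g` in `formula_add()` may carry negative counts (a signed
#'   adduct delta).
#' @return A `mol_formula`.
#' @examples
#' formula_add("CH3", c(H = 1))
#' formula_subtract("C2H6O", "H2O")
#' @export
formula_add <- function(f, g) {
  f <- as_mol_formula(f)
  g <- if (is.character(g)) parse_formula(g) else unlist(g)
  all_el <- union(names(f), names(g))
  if (length(all_el) == 0) return(mol_formula())
  .check_elements(all_el)
  total <- stats::setNames(integer(length(all_el)), all_el)
  total[names(f)] <- total[names(f)] + as.integer(f)
  total[names(g)] <- total[names(g)] + as.integer(g)
  if (any(total < 0)) {
    stop(sprintf("negative element count after combination: %s",
                 paste(names(total)[total < 0], collapse = ", ")),
         call. = FALSE)
  }
  mol_formula(total)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f, g) {
  g <- as_mol_formula(g)
  formula_add(f, stats::setNames(-as.integer(g), names(g)))
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the element's most
#' abundant isotope. Additive: `mass(f + g) = mass(f) + mass(g)`.
#'
#' @param f Formula (any form accepted by [as_mol_formula()]).
#' @return Mass in Da; `0` for the empty formula.
#' @examples
#' monoisotopic_mass("C11H15NO2")  # 193.11028
#' @export
monoisotopic_mass <- function(f) {
  f <- as_mol_formula(f)
  if (length(f) == 0) return(0)
  sum(as.numeric(f) * .element_mass(names(f)))
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = 1 + sum over elements of count * (valence - 2) / 2, using the
#' standard valences tabulated in [element_table()]. Reported as an
#' annotation of chemical plausibility; no filtering is done on it by
#' default.
#'
#' @param f Formula (any form accepted by [as_mol_formula()]).
#' @return A double (can be half-integer or negative).
#' @examples
#' rdbe("C11H15NO2")  # 5
#' rdbe("CH4")        # 0
#' @export
rdbe <- function(f) {
  f <- as_mol_formula(f)
  if (length(f) == 0) return(1)
  v <- .valences[names(f)]
  1 + sum(as.numeric(f) * (v - 2)) / 2
}
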
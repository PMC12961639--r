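#' Per-element count ranges for formula enumeration
#'
#' Builds a validated range set from a compact string such as
#' `"C0-100H0-200N0-20"`, from a named list of `c(min, max)` pairs, or
#' from a tibble with columns `element`, `min`, `max`. Elements must be
#' known to [element_table()] and every range must satisfy
#' `0 <= min <= max`.
#'
#' @param x Ranges in any of the accepted forms.
#' @return A tibble with columns `element`, `min`, `max`
#'   (class `element_ranges`).
#' @examples
#' element_ranges("C0-10H0-20N0-2O0-3")
#' element_ranges(list(C = c(0, 10), H = c(0, 20)))
#' @export
element_ranges <- function(x) {
  if (inherits(x, "element_ranges")) return(x)
  if (is.character(x) && length(x) == 1) {
    m <- stringr::str_match_all(
      x, "([A-Z][a-z]?)\\s*([0-9]+)\\s*-\\s*([0-9]+)|(\\S)"
    )[[1]]
    bad <- m[, 5][!is.na(m[, 5])]
    if (nrow(m) == 0 || length(bad) > 0) {
      stop(sprintf("malformed range string near '%s'",
                   if (length(bad)) bad[[1]] else x), call. = FALSE)
    }
    x <- tibble::tibble(element = m[, 2],
                        min = as.integer(m[, 3]),
                        max = as.integer(m[, 4]))
  } else if (is.list(x) && !is.data.frame(x)) {
    x <- tibble::tibble(
      element = names(x),
      min = purrr::map_int(x, ~ as.integer(.x[[1]])),
      max = purrr::map_int(x, ~ as.integer(.x[[2]]))
    )
  } else {
    x <- tibble::as_tibble(x)
    stopifnot(all(c("element", "min", "max") %in% names(x)))
  }
  .check_elements(x$element, context = "element ranges")
  if (anyDuplicated(x$element)) {
    stop("duplicate element in ranges", call. = FALSE)
  }
  if (any(x$min < 0) || any(x$min > x$max)) {
    stop("ranges must satisfy 0 <= min <= max", call. = FALSE)
  }
  structure(tibble::as_tibble(x[c("element", "min", "max")]),
            class = c("element_ranges", class(tibble::tibble())))
}

#' Default element-range preset for broad small-molecule screening
#'
#' C 0-100, H 0-200, N 0-20, O 0-20, S 0-10, F 0-3, Cl 0-3, Br 0-3,
#' B 0-3: wide enough for most small-molecule dereplication work in
#' positive-mode ESI, including boron- and halogen-containing species.
#'
#' @return An `element_ranges` tibble.
#' @export
default_element_ranges <- function() {
  element_ranges("C0-100H0-200N0-20O0-20S0-10F0-3Cl0-3Br0-3B0-3")
}
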
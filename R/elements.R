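#' Physical constants used in ion mass arithmetic
#'
#' Electron and proton rest masses in unified atomic mass units (Da).
#' Protonation adds the mass of a hydrogen atom minus one electron
#' (1.00727646688 Da), not the mass of a neutral hydrogen atom; at
#' m/z 100-200 the 0.55 mDa difference is several ppm and matters.
#'
#' @format Named numeric scalars.
#' @name ms_constants
NULL

#' @rdname ms_constants
#' @export
ELECTRON_MASS <- 0.000548579909

#' @rdname ms_constants
#' @export
PROTON_MASS <- 1.007276466879

# Isotope masses (Da) and relative abundances, IUPAC/NIST standard values.
# Within each element the most abundant isotope is listed first and defines
# the monoisotopic mass. Abundances sum to 1 within 1e-6.
.isotope_data <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785), ab = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.00335483507), ab = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088982), ab = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317012, 17.9991610043),
            ab = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(mass = 30.97376163, ab = 1),
  F  = list(mass = 18.99840322, ab = 1),
  Cl = list(mass = c(34.96885268, 36.96590259), ab = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183371, 80.9162906), ab = c(0.5069, 0.4931)),
  I  = list(mass = 126.904473, ab = 1),
  B  = list(mass = c(11.0093054, 10.0129370), ab = c(0.801, 0.199)),
  Si = list(mass = c(27.9769265325, 28.9764946653, 29.9737701340),
            ab = c(0.92223, 0.04685, 0.03092)),
  Na = list(mass = 22.9897692809, ab = 1),
  K  = list(mass = c(38.96370668, 40.96182576, 39.96399848),
            ab = c(0.932581, 0.067302, 0.000117))
)

# Standard valences used by the ring-plus-double-bond annotation.
.valences <- c(
  H = 1, C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4, Na = 1, K = 1
)

#' Element reference table
#'
#' Monoisotopic masses, isotope distributions and standard valences for the
#' element alphabet supported by formula parsing, enumeration and isotope
#' simulation. One row per element; the `isotopes` list-column holds a
#' tibble of (mass, abundance) pairs per element, most abundant first.
#'
#' @return A tibble with columns `element`, `monoisotopic_mass`, `valence`
#'   and list-column `isotopes`.
#' @examples
#' element_table()
#' @export
element_table <- function() {
  tibble::tibble(
    element = names(.isotope_data),
    monoisotopic_mass = purrr::map_dbl(.isotope_data, ~ .x$mass[[1]]),
    valence = unname(.valences[names(.isotope_data)]),
    isotopes = purrr::map(.isotope_data, ~ tibble::tibble(
      mass = .x$mass, abundance = .x$ab
    ))
  )
}

.known_elements <- function() names(.isotope_data)

.element_mass <- function(symbols) {
  m <- purrr::map_dbl(.isotope_data[symbols], ~ .x$mass[[1]])
  names(m) <- symbols
  m
}

.check_elements <- function(symbols, context = "formula") {
  bad <- setdiff(symbols, .known_elements())
  if (length(bad) > 0) {
    stop(sprintf("unknown element symbol%s in %s: %s",
                 if (length(bad) > 1) "s" else "", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(symbols)
}
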
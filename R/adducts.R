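#' Built-in adduct registry
#'
#' The adducts (ionization types) the package knows out of the box. Each
#' adduct is a formula delta applied to the neutral molecule M plus a
#' charge; the electron count follows from the charge. Custom adducts can
#' be added through a configuration file (see [read_config()]) or built
#' directly with [adduct()].
#'
#' @return A tibble with columns `name`, `charge` and list-column `delta`
#'   (named integer vectors of signed element-count changes).
#' @examples
#' adduct_registry()
#' @export
adduct_registry <- function() {
  reg <- list(
    "[M+H]+"   = list(delta = c(H = 1L),          charge = 1L),
    "[M+Na]+"  = list(delta = c(Na = 1L),         charge = 1L),
    "[M+K]+"   = list(delta = c(K = 1L),          charge = 1L),
    "[M+NH4]+" = list(delta = c(N = 1L, H = 4L),  charge = 1L),
    "[M]+"     = list(delta = stats::setNames(integer(), character()),
                      charge = 1L),
    "[M-H]-"   = list(delta = c(H = -1L),         charge = -1L),
    "[M+Cl]-"  = list(delta = c(Cl = 1L),         charge = -1L)
  )
  tibble::tibble(
    name = names(reg),
    charge = purrr::map_int(reg, "charge"),
    delta = purrr::map(reg, "delta")
  )
}

#' Define or look up an adduct
#'
#' With only `name`, looks the adduct up in the built-in registry
#' (optionally extended by `extra`, e.g. from a config file). With
#' `delta` and `charge` given, defines a new adduct.
#'
#' @param name Adduct name, e.g. `"[M+H]+"`. Unicode minus signs are
#'   normalized to ASCII.
#' @param delta Named integer vector of signed element-count changes
#'   relative to the neutral molecule (only for user-defined adducts).
#' @param charge Non-zero integer charge (only for user-defined adducts).
#' @param extra Optional tibble in the shape of [adduct_registry()] with
#'   additional adducts, consulted before the built-ins.
#' @return A list of class `adduct` with fields `name`, `delta`, `charge`.
#' @examples
#' adduct("[M+H]+")
#' adduct("[M+2H]2+", delta = c(H = 2), charge = 2)
#' @export
adduct <- function(name, delta = NULL, charge = NULL, extra = NULL) {
  if (inherits(name, "adduct")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  name <- gsub("−", "-", name)
  if (is.null(delta) && is.null(charge)) {
    reg <- adduct_registry()
    if (!is.null(extra)) reg <- dplyr::bind_rows(extra, reg)
    hit <- which(reg$name == name)
    if (length(hit) == 0) {
      stop(sprintf("unknown adduct '%s'; define it with delta= and charge=",
                   name), call. = FALSE)
    }
    delta <- reg$delta[[hit[[1]]]]
    charge <- reg$charge[[hit[[1]]]]
  }
  if (is.null(charge) || charge == 0 || charge != round(charge)) {
    stop("adduct charge must be a non-zero integer", call. = FALSE)
  }
  delta <- unlist(delta)
  if (length(delta) > 0) {
    .check_elements(names(delta), context = sprintf("adduct '%s'", name))
    storage.mode(delta) <- "integer"
    delta <- delta[delta != 0L]
  } else {
    delta <- stats::setNames(integer(), character())
  }
  structure(list(name = name, delta = delta, charge = as.integer(charge)),
            class = "adduct")
}

#' @export
print.adduct <- function(x, ...) {
  d <- if (length(x$delta) == 0) "M unchanged" else
    paste(sprintf("%+d %s", x$delta, names(x$delta)), collapse = ", ")
  cat(sprintf("<adduct> %s  (%s; charge %+d)\n", x$name, d, x$charge))
  invisible(x)
}

#' m/z of an ionized formula
#'
#' Applies the adduct's formula delta to the neutral composition, removes
#' `charge` electrons (adds them for negative charge) and divides by the
#' absolute charge:
#' `mz = (mass(M + delta) - charge * m_e) / |charge|`.
#' For `[M+H]+` this equals the neutral mass plus the proton mass
#' 1.00727646688 Da.
#'
#' @param f Neutral formula (any form accepted by [as_mol_formula()]).
#' @param a Adduct (an `adduct` object or a registry name).
#' @return The ion m/z in Th (Da per unit charge).
#' @examples
#' ion_mz("C11H15NO2", "[M+H]+")  # 194.11756
#' @export
ion_mz <- function(f, a = "[M+H]+") {
  a <- adduct(a)
  ion <- formula_add(f, a$delta)  # errors if the delta removes absent atoms
  (monoisotopic_mass(ion) - a$charge * ELECTRON_MASS) / abs(a$charge)
}

#' Neutral monoisotopic mass implied by an observed ion m/z
#'
#' Inverse of [ion_mz()]: the monoisotopic mass a neutral molecule must
#' have for its adduct ion to sit at `mz`.
#'
#' @param mz Observed ion m/z.
#' @param a Adduct.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz, a = "[M+H]+") {
  a <- adduct(a)
  delta_mass <- if (length(a$delta) == 0) 0 else
    sum(as.numeric(a$delta) * .element_mass(names(a$delta)))
  mz * abs(a$charge) + a$charge * ELECTRON_MASS - delta_mass
}

#' Signed relative mass error in parts per million
#'
#' `(observed - calculated) / calculated * 1e6`. The error is signed and
#' computed against the calculated (theoretical) value; tolerance filters
#' throughout the package compare `abs(ppm_error(...))` to the tolerance.
#'
#' @param observed Observed m/z or mass.
#' @param calculated Theoretical m/z or mass; must be positive.
#' @return Signed ppm error (vectorized).
#' @examples
#' ppm_error(194.1173, ion_mz("C11H15NO2", "[M+H]+"))
#' @export
ppm_error <- function(observed, calculated) {
  if (any(calculated <= 0)) {
    stop("calculated mass must be positive", call. = FALSE)
  }
  (observed - calculated) / calculated * 1e6
}
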
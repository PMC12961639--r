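#' Construct a centroided mass spectrum
#'
#' A spectrum is a tibble of peaks (`mz`, `intensity`), sorted by m/z,
#' with optional precursor m/z, adduct and free-form metadata carried as
#' attributes. All spectrum-consuming functions in the package also
#' accept a plain data frame with `mz` and `intensity` columns.
#'
#' @param mz Numeric vector of peak m/z values (need not be pre-sorted;
#'   duplicates allowed). Alternatively a data frame with `mz` and
#'   `intensity` columns.
#' @param intensity Numeric vector of non-negative, finite intensities.
#' @param precursor_mz Optional precursor ion m/z.
#' @param precursor_adduct Optional adduct name, e.g. `"[M+H]+"`.
#' @param metadata Optional named list (title, source id, activation ...).
#' @return A tibble of class `ms_spectrum`.
#' @examples
#' spectrum(c(105.0697, 133.0647, 163.0752), c(80, 45, 100),
#'          precursor_mz = 194.1173, precursor_adduct = "[M+H]+")
#' @export
spectrum <- function(mz, intensity = NULL, precursor_mz = NULL,
                     precursor_adduct = NULL, metadata = list()) {
  if (is.data.frame(mz)) {
    stopifnot(all(c("mz", "intensity") %in% names(mz)))
    intensity <- mz$intensity
    mz <- mz$mz
  }
  if (length(mz) == 0) stop("a spectrum needs at least one peak", call. = FALSE)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("peak m/z values must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  o <- order(mz)
  out <- tibble::tibble(mz = as.numeric(mz[o]),
                        intensity = as.numeric(intensity[o]))
  attr(out, "precursor_mz") <- precursor_mz
  attr(out, "precursor_adduct") <- precursor_adduct
  attr(out, "metadata") <- metadata
  class(out) <- c("ms_spectrum", class(out))
  out
}

#' @export
print.ms_spectrum <- function(x, ...) {
  pm <- attr(x, "precursor_mz")
  md <- attr(x, "metadata")
  cat(sprintf("<ms_spectrum> %d peaks%s%s\n", nrow(x),
              if (!is.null(pm)) sprintf(", precursor %.4f", pm) else "",
              if (!is.null(md$title)) sprintf(", '%s'", md$title) else ""))
  NextMethod()
}

#' Precursor m/z of a spectrum
#' @param s An `ms_spectrum`.
#' @return The precursor m/z or `NULL`.
#' @export
precursor_mz <- function(s) attr(s, "precursor_mz")

# tolerate plain data frames wherever a spectrum is expected
.peaks_of <- function(s) {
  stopifnot(is.data.frame(s), all(c("mz", "intensity") %in% names(s)))
  tibble::tibble(mz = as.numeric(s$mz), intensity = as.numeric(s$intensity))
}

#' Pick the most intense peak near a target m/z
#'
#' Returns the most intense peak within `tol_ppm` of `target`; on an
#' intensity tie the peak closer in m/z wins. Typical use: selecting the
#' monoisotopic ion of interest from a survey scan before formula
#' enumeration.
#'
#' @param s Spectrum.
#' @param target Target m/z.
#' @param tol_ppm Window half-width in ppm.
#' @return One-row tibble with `mz` and `intensity`.
#' @export
pick_peak <- function(s, target, tol_ppm = 10) {
  pk <- .peaks_of(s)
  lim <- tol_ppm * 1e-6 * target
  in_win <- which(abs(pk$mz - target) <= lim)
  if (length(in_win) == 0) {
    stop(sprintf("no peak within %g ppm of %g", tol_ppm, target),
         call. = FALSE)
  }
  cand <- pk[in_win, ]
  cand <- cand[order(-cand$intensity, abs(cand$mz - target)), ]
  cand[1, ]
}

#' Assign elemental subformulas to MS/MS fragment ions
#'
#' For each fragment m/z, searches all compositions `g` that fit inside
#' the ionized precursor composition (element-wise
#' `0 <= g <= precursor + adduct delta`) and whose single-charge ion m/z
#' (mass minus one electron for positive mode, plus one for negative)
#' lies within `tol_ppm`. A fragment is assigned when at least one such
#' subformula exists; the consistency score is the percentage of
#' assigned fragments, by count — fragment intensities play no role.
#'
#' @param precursor Neutral precursor formula.
#' @param a Adduct that formed the precursor ion; its charge sign decides
#'   whether fragments are modeled as cations or anions.
#' @param fragments Numeric vector of fragment m/z values (non-empty).
#' @param tol_ppm Mass tolerance in ppm.
#' @return A list with `assignments` (tibble: `fragment_mz`, `assigned`,
#'   and list-column `matches`, each a tibble of `formula`, `mz`,
#'   `ppm_error`) and `percent_assigned`.
#' @examples
#' assign_fragments("C11H15NO2", "[M+H]+",
#'                  c(105.0697, 133.0647, 163.0752), tol_ppm = 5)
#' @export
assign_fragments <- function(precursor, a = "[M+H]+", fragments,
                             tol_ppm = 5) {
  if (length(fragments) == 0) stop("no fragments given", call. = FALSE)
  stopifnot(is.numeric(fragments), all(fragments > 0), tol_ppm > 0)
  a <- adduct(a)
  ion <- formula_add(as_mol_formula(precursor), a$delta)
  if (length(ion) == 0) stop("empty precursor composition", call. = FALSE)
  ranges <- element_ranges(tibble::tibble(
    element = names(ion), min = 0L, max = as.integer(ion)
  ))
  esign <- if (a$charge >= 0) 1 else -1

  rows <- purrr::map(fragments, function(fmz) {
    # fragment ion m/z window -> window on the fragment's composition mass
    lo <- fmz * (1 - tol_ppm * 1e-6) + esign * ELECTRON_MASS
    hi <- fmz * (1 + tol_ppm * 1e-6) + esign * ELECTRON_MASS
    hits <- .enumerate_mass_window(lo, hi, ranges)
    hits <- purrr::keep(hits, ~ sum(.x) > 0)
    if (length(hits) == 0) {
      return(tibble::tibble(
        fragment_mz = fmz, assigned = FALSE,
        matches = list(tibble::tibble(formula = character(), mz = double(),
                                      ppm_error = double()))
      ))
    }
    fs <- purrr::map(hits, mol_formula)
    m <- tibble::tibble(
      formula = purrr::map_chr(fs, formula_string),
      mz = purrr::map_dbl(fs, monoisotopic_mass) - esign * ELECTRON_MASS
    )
    m$ppm_error <- ppm_error(fmz, m$mz)
    m <- m[order(abs(m$ppm_error), m$formula), ]
    tibble::tibble(fragment_mz = fmz, assigned = TRUE, matches = list(m))
  })
  assignments <- dplyr::bind_rows(rows)
  list(
    assignments = assignments,
    percent_assigned = 100 * sum(assignments$assigned) / nrow(assignments)
  )
}
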
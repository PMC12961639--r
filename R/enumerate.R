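# Exhaustive search over element-count boxes for compositions whose total
# monoisotopic mass falls in [lo, hi]. Depth-first over elements in
# descending-mass order, pruning a branch as soon as the remaining elements
# cannot bring the running mass into the window. The lightest element is
# never looped: its admissible counts are solved directly from the residual
# window, which is what makes hydrogen-rich searches cheap.
.enumerate_mass_window <- function(lo, hi, ranges) {
  el <- ranges$element
  mass <- .element_mass(el)
  ord <- order(mass, decreasing = TRUE)
  el <- el[ord]
  mn <- ranges$min[ord]
  mx <- ranges$max[ord]
  m <- unname(mass[el])
  k <- length(el)
  # suffix bounds: least/greatest mass still addable from element i onward
  suf_min <- rev(cumsum(rev(mn * m)))
  suf_max <- rev(cumsum(rev(mx * m)))
  suf_min <- c(suf_min, 0)
  suf_max <- c(suf_max, 0)

  acc <- vector("list", 64L)
  n_acc <- 0L
  push <- function(counts) {
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) acc[[2L * n_acc]] <<- NULL
    acc[[n_acc]] <<- counts
  }
  counts <- integer(k)

  recurse <- function(i, total) {
    if (i == k) {
      # solve the last (lightest) element's count from the residual window
      c_lo <- max(mn[k], ceiling((lo - total) / m[k] - 1e-9))
      c_hi <- min(mx[k], floor((hi - total) / m[k] + 1e-9))
      if (c_lo <= c_hi) {
        for (cc in c_lo:c_hi) {
          counts[k] <<- as.integer(cc)
          push(counts)
        }
      }
      return(invisible())
    }
    c_max <- min(mx[i], floor((hi - total - suf_min[i + 1L]) / m[i] + 1e-9))
    c_min <- max(mn[i], ceiling((lo - total - suf_max[i + 1L]) / m[i] - 1e-9))
    if (c_max < c_min) return(invisible())
    for (cc in c_min:c_max) {
      counts[i] <<- as.integer(cc)
      recurse(i + 1L, total + cc * m[i])
    }
    counts[i] <<- 0L
    invisible()
  }

  if (k == 0L) {
    if (lo <= 0 && 0 <= hi) push(integer(0))
  } else {
    recurse(1L, 0)
  }
  out <- acc[seq_len(n_acc)]
  lapply(out, function(x) stats::setNames(x, el))
}

#' Enumerate candidate molecular formulas for an observed m/z
#'
#' Finds every elemental composition inside the per-element count ranges
#' whose adduct ion m/z lies within `tol_ppm` of the observed m/z. The
#' search is complete: it returns exactly the set an exhaustive nested
#' loop over all compositions would, at a cost that scales with the
#' number of compositions below the mass ceiling rather than the full
#' range product. No chemical-plausibility filter is applied; RDBE is
#' reported as an annotation only.
#'
#' @param observed_mz Observed ion m/z (positive).
#' @param a Adduct (object or registry name); default `"[M+H]+"`.
#' @param tol_ppm Mass tolerance in ppm (positive).
#' @param ranges Element ranges (anything [element_ranges()] accepts);
#'   default [default_element_ranges()].
#' @return A tibble of candidates sorted by `abs(ppm_error)` ascending
#'   (ties by formula text): columns `formula`, `counts` (list), `mz`
#'   (theoretical ion m/z), `ppm_error`, `rdbe`, `has_known_structures`,
#'   `bioactive_or_natural`.
#' @examples
#' enumerate_formulas(61.0284, "[M+H]+", tol_ppm = 10,
#'                    ranges = "C0-3H0-8N0-2O0-3")
#' @export
enumerate_formulas <- function(observed_mz, a = "[M+H]+", tol_ppm = 5,
                               ranges = default_element_ranges()) {
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1,
            observed_mz > 0)
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1 || tol_ppm <= 0) {
    stop("tol_ppm must be a positive number", call. = FALSE)
  }
  a <- adduct(a)
  ranges <- element_ranges(ranges)

  # ion m/z window -> window on the neutral monoisotopic mass
  lo <- neutral_mass(observed_mz * (1 - tol_ppm * 1e-6), a)
  hi <- neutral_mass(observed_mz * (1 + tol_ppm * 1e-6), a)

  # the adduct delta must be removable from the ion, i.e. the neutral M
  # plus delta must be non-negative; enforce by shifting mins where the
  # delta is negative (e.g. [M-H]- requires at least one H in M)
  mins <- stats::setNames(ranges$min, ranges$element)
  neg <- a$delta[a$delta < 0]
  if (length(neg) > 0) {
    need <- -neg
    for (e in names(need)) {
      if (!e %in% ranges$element) return(.empty_candidates())
      mins[e] <- max(mins[e], need[[e]])
    }
    if (any(mins[ranges$element] > ranges$max)) return(.empty_candidates())
    ranges$min <- unname(mins[ranges$element])
  }

  hits <- .enumerate_mass_window(lo, hi, ranges)
  if (length(hits) == 0) return(.empty_candidates())

  cands <- purrr::map(hits, mol_formula)
  out <- tibble::tibble(
    formula = purrr::map_chr(cands, formula_string),
    counts = cands,
    mz = purrr::map_dbl(cands, ion_mz, a = a),
    rdbe = purrr::map_dbl(cands, rdbe)
  )
  out$ppm_error <- ppm_error(observed_mz, out$mz)
  # the window arithmetic is exact, but re-verify against the definition
  out <- out[abs(out$ppm_error) <= tol_ppm + 1e-9, , drop = FALSE]
  out$has_known_structures <- FALSE
  out$bioactive_or_natural <- FALSE
  out <- out[order(abs(out$ppm_error), out$formula), , drop = FALSE]
  out[c("formula", "counts", "mz", "ppm_error", "rdbe",
        "has_known_structures", "bioactive_or_natural")]
}

.empty_candidates <- function() {
  tibble::tibble(
    formula = character(), counts = list(), mz = double(),
    ppm_error = double(), rdbe = double(),
    has_known_structures = logical(), bioactive_or_natural = logical()
  )
}
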
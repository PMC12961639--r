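#' Cosine similarity between two centroided spectra
#'
#' Peaks of the two spectra are paired one-to-one within `tol` Da,
#' greedily by descending intensity product (ties broken by lower m/z),
#' and the score is
#' `100 * sum(paired Ia * Ib) / (||Ia|| * ||Ib||)`
#' with the norms taken over all peaks of each spectrum. Symmetric, in
#' `[0, 100]`, and exactly 100 for a spectrum against itself. Intensities
#' are used raw by default; `sqrt_intensity = TRUE` applies square-root
#' weighting first, which de-emphasizes dominant peaks.
#'
#' @param s1,s2 Spectra (anything with `mz` and `intensity` columns).
#' @param tol Peak-pairing tolerance in Da; default 0.01.
#' @param sqrt_intensity Apply square-root intensity weighting.
#' @return Similarity percentage in `[0, 100]`.
#' @examples
#' a <- spectrum(c(100, 150), c(1, 2))
#' b <- spectrum(c(100, 150), c(2, 1))
#' cosine_match(a, b)  # 80
#' @export
cosine_match <- function(s1, s2, tol = 0.01, sqrt_intensity = FALSE) {
  p1 <- .peaks_of(s1); p2 <- .peaks_of(s2)
  i1 <- p1$intensity; i2 <- p2$intensity
  if (sqrt_intensity) { i1 <- sqrt(i1); i2 <- sqrt(i2) }
  d <- abs(outer(p1$mz, p2$mz, `-`))
  ok <- which(d <= tol, arr.ind = TRUE)
  if (nrow(ok) == 0) return(0)
  prod <- i1[ok[, 1]] * i2[ok[, 2]]
  ord <- order(-prod, p1$mz[ok[, 1]], p2$mz[ok[, 2]])
  ok <- ok[ord, , drop = FALSE]
  used1 <- logical(nrow(p1)); used2 <- logical(nrow(p2))
  contrib <- numeric(0)
  for (r in seq_len(nrow(ok))) {
    i <- ok[r, 1]; j <- ok[r, 2]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE
      contrib <- c(contrib, i1[i] * i2[j])
    }
  }
  # summation in sorted order so a self-match accumulates the numerator
  # and the norms identically, making cosine_match(s, s) exactly 100
  dot <- sum(sort(contrib))
  qa <- sum(sort(i1^2)); qb <- sum(sort(i2^2))
  if (qa == 0 || qb == 0) return(0)
  if (dot * dot >= qa * qb) return(100)
  dot / sqrt(qa * qb) * 100
}

#' Build a spectral library
#'
#' A library is a tibble of annotated reference spectra indexed (sorted)
#' by precursor m/z. Every entry must have a precursor m/z; annotations
#' (compound name, formula, structure, source database) travel with the
#' entry and come back attached to search hits.
#'
#' @param entries A data frame with at least `precursor_mz` and a `peaks`
#'   list-column of spectra (or peak tibbles). Optional columns: `id`,
#'   `name`, `formula`, `structure`, `source`.
#' @return A tibble of class `spectral_library`, sorted by precursor m/z.
#' @export
spectral_library <- function(entries) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("precursor_mz", "peaks") %in% names(entries)))
  if (any(!is.finite(entries$precursor_mz))) {
    stop("every library entry needs a finite precursor m/z", call. = FALSE)
  }
  if (!"id" %in% names(entries)) {
    entries$id <- sprintf("entry_%03d", seq_len(nrow(entries)))
  }
  for (col in c("name", "formula", "structure", "source")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_character_
  }
  entries <- entries[order(entries$precursor_mz), , drop = FALSE]
  class(entries) <- c("spectral_library", class(tibble::tibble()))
  entries
}

#' Match a query MS/MS spectrum against a spectral library
#'
#' Library entries are prefiltered to those whose precursor m/z lies
#' within `precursor_tol_ppm` of the query's precursor, then ranked by
#' [cosine_match()] against the query, descending.
#'
#' @param query Spectrum with a precursor m/z (see [spectrum()]).
#' @param lib A [spectral_library()].
#' @param precursor_tol_ppm Precursor prefilter window in ppm.
#' @param peak_tol Peak-pairing tolerance in Da for the cosine.
#' @param sqrt_intensity Passed to [cosine_match()].
#' @return The matching entries with a `score` column, sorted descending;
#'   zero rows when nothing falls in the precursor window.
#' @export
match_against_library <- function(query, lib, precursor_tol_ppm = 10,
                                  peak_tol = 0.01, sqrt_intensity = FALSE) {
  pmz <- precursor_mz(query)
  if (is.null(pmz)) {
    stop("query spectrum has no precursor m/z", call. = FALSE)
  }
  lim <- precursor_tol_ppm * 1e-6 * pmz
  hits <- lib[abs(lib$precursor_mz - pmz) <= lim, , drop = FALSE]
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    hits$score <- double()
    return(hits)
  }
  hits$score <- purrr::map_dbl(
    hits$peaks, cosine_match,
    s2 = query, tol = peak_tol, sqrt_intensity = sqrt_intensity
  )
  hits[order(-hits$score), , drop = FALSE]
}

#' Search a spectral library by fragment ions
#'
#' Finds library spectra containing at least `min_peaks` of the query
#' fragment m/z values within `tol` Da, and ranks them by cosine
#' similarity between the fragment set (taken with unit intensities) and
#' the entry's peaks. Annotations on the hits support substructure
#' frequency inspection downstream.
#'
#' @param fragments Numeric vector of fragment m/z values (non-empty).
#' @param lib A [spectral_library()].
#' @param tol Fragment match tolerance in Da.
#' @param min_peaks Minimum number of matched fragments (>= 1).
#' @return Matching entries with `n_matched` and `score`, sorted by
#'   score descending; empty when `min_peaks` exceeds the query size.
#' @export
search_by_fragments <- function(fragments, lib, tol = 0.01, min_peaks = 1) {
  stopifnot(length(fragments) >= 1, is.numeric(fragments), min_peaks >= 1)
  query <- spectrum(fragments, rep(1, length(fragments)))
  out <- tibble::as_tibble(lib)
  out$n_matched <- purrr::map_int(out$peaks, function(p) {
    p <- .peaks_of(p)
    sum(purrr::map_lgl(fragments, ~ any(abs(p$mz - .x) <= tol)))
  })
  out <- out[out$n_matched >= min_peaks, , drop = FALSE]
  if (nrow(out) == 0) {
    out$score <- double()
    return(out)
  }
  out$score <- purrr::map_dbl(out$peaks, cosine_match, s2 = query, tol = tol)
  out[order(-out$score), , drop = FALSE]
}
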
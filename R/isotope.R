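# -- isotopologue distribution arithmetic -------------------------------
# A distribution is a data frame (mass, prob), mass ascending, probs > 0.
# Convolution of two distributions: all pairwise mass sums with product
# probabilities, then centroid-merging of isotopologues closer than
# merge_tol. A fixed absolute floor (independent of the user-facing prune
# threshold) keeps intermediate products small without affecting any peak
# that could survive final pruning.
.PROB_FLOOR <- 1e-12

.dist_merge <- function(mass, prob, merge_tol) {
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  grp <- cumsum(c(1, diff(mass) > merge_tol))
  m <- as.numeric(tapply(mass * prob, grp, sum) / tapply(prob, grp, sum))
  p <- as.numeric(tapply(prob, grp, sum))
  keep <- p > .PROB_FLOOR
  list(mass = m[keep], prob = p[keep])
}

.dist_convolve <- function(a, b, merge_tol) {
  mass <- outer(a$mass, b$mass, `+`)
  prob <- outer(a$prob, b$prob, `*`)
  .dist_merge(as.vector(mass), as.vector(prob), merge_tol)
}

# n-fold self-convolution of one element's isotope distribution by
# binary exponentiation
.element_dist <- function(element, n, merge_tol) {
  iso <- .isotope_data[[element]]
  base <- list(mass = iso$mass, prob = iso$ab)
  if (n == 1L) return(.dist_merge(base$mass, base$prob, merge_tol))
  result <- NULL
  sq <- base
  while (n > 0L) {
    if (n %% 2L == 1L) {
      result <- if (is.null(result)) sq else .dist_convolve(result, sq, merge_tol)
    }
    n <- n %/% 2L
    if (n > 0L) sq <- .dist_convolve(sq, sq, merge_tol)
  }
  result
}

#' Simulate the isotopic pattern of an ionized formula
#'
#' Computes the isotopologue distribution of the ion formed from formula
#' `f` under adduct `a` by iterative convolution of per-element isotope
#' distributions. Isotopologues closer than `merge_tol` Da are merged
#' into abundance-weighted centroids (unresolvable at typical
#' resolutions); after normalizing the most abundant species to 100,
#' peaks below `prune * 100` are discarded.
#'
#' @param f Non-empty neutral formula (any form [as_mol_formula()] takes).
#' @param a Adduct; the delta atoms contribute their own isotopes and the
#'   charge shifts and scales m/z exactly as in [ion_mz()].
#' @param prune Relative abundance threshold in (0, 1); default `1e-4`.
#' @param merge_tol Centroid merge tolerance in Da; default `1e-3`.
#' @return A tibble of class `isotope_pattern` with columns `mz`
#'   (ascending) and `abundance` (max exactly 100).
#' @examples
#' simulate_pattern("C11H15NO2", "[M+H]+")
#' @export
simulate_pattern <- function(f, a = "[M+H]+", prune = 1e-4,
                             merge_tol = 1e-3) {
  f <- as_mol_formula(f)
  if (length(f) == 0) stop("cannot simulate an empty formula", call. = FALSE)
  if (!is.numeric(prune) || prune <= 0 || prune >= 1) {
    stop("prune must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(merge_tol) || merge_tol <= 0) {
    stop("merge_tol must be positive", call. = FALSE)
  }
  a <- adduct(a)
  ion <- formula_add(f, a$delta)
  dist <- NULL
  for (e in names(ion)) {
    d <- .element_dist(e, ion[[e]], merge_tol)
    dist <- if (is.null(dist)) d else .dist_convolve(dist, d, merge_tol)
  }
  mz <- (dist$mass - a$charge * ELECTRON_MASS) / abs(a$charge)
  ab <- dist$prob / max(dist$prob) * 100
  keep <- ab >= prune * 100
  out <- tibble::tibble(mz = mz[keep], abundance = ab[keep])
  out <- out[order(out$mz), ]
  class(out) <- c("isotope_pattern", class(out))
  out
}

# one-to-one greedy alignment of two m/z vectors: candidate pairs within
# tolerance, accepted in order of ascending |delta m/z|
.align_peaks <- function(mz_a, mz_b, tol, tol_unit = c("ppm", "da")) {
  tol_unit <- match.arg(tol_unit)
  if (length(mz_a) == 0 || length(mz_b) == 0) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  d <- abs(outer(mz_a, mz_b, `-`))
  lim <- if (tol_unit == "ppm") tol * 1e-6 * abs(mz_a) else
    rep(tol, length(mz_a))
  ok <- which(d <= lim, arr.ind = TRUE)
  if (nrow(ok) == 0) return(tibble::tibble(i = integer(), j = integer()))
  ord <- order(d[ok])
  ok <- ok[ord, , drop = FALSE]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(ok))
  for (r in seq_len(nrow(ok))) {
    i <- ok[r, 1]; j <- ok[r, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  ok <- ok[keep, , drop = FALSE]
  tibble::tibble(i = ok[, 1], j = ok[, 2])
}

#' Isotopic-pattern similarity between an experimental spectrum and a
#' simulated pattern
#'
#' Pattern peaks are aligned one-to-one to the nearest experimental peaks
#' within `match_tol` (closest pairs first). The score is the cosine of
#' the aligned abundance vectors, times 100; unmatched peaks on either
#' side contribute a zero on the other side, so extra or missing peaks
#' pull the score down symmetrically. Invariant under uniform intensity
#' scaling of the experimental spectrum.
#'
#' @param experimental A spectrum (anything with `mz` and `intensity`
#'   columns, e.g. from [spectrum()]), at least one peak.
#' @param pattern An `isotope_pattern` from [simulate_pattern()].
#' @param match_tol Peak-match tolerance; default 5.
#' @param tol_unit `"ppm"` (default) or `"da"`.
#' @return Similarity percentage in `[0, 100]`.
#' @export
isotopic_similarity <- function(experimental, pattern, match_tol = 5,
                                tol_unit = c("ppm", "da")) {
  tol_unit <- match.arg(tol_unit)
  exp_pk <- .peaks_of(experimental)
  if (nrow(exp_pk) == 0) stop("experimental spectrum is empty", call. = FALSE)
  stopifnot(all(c("mz", "abundance") %in% names(pattern)))
  al <- .align_peaks(pattern$mz, exp_pk$mz, match_tol, tol_unit)
  # aligned vectors over the union of peaks
  n <- nrow(pattern) + nrow(exp_pk) - nrow(al)
  va <- numeric(n); vb <- numeric(n)
  va[seq_len(nrow(pattern))] <- pattern$abundance
  vb[al$i] <- exp_pk$intensity[al$j]
  extra <- setdiff(seq_len(nrow(exp_pk)), al$j)
  if (length(extra) > 0) {
    vb[nrow(pattern) + seq_along(extra)] <- exp_pk$intensity[extra]
  }
  .cosine_score(va, vb)
}

# cosine of two aligned non-negative vectors, as a percentage; exact 100
# at Cauchy-Schwarz equality (identical or proportional vectors)
.cosine_score <- function(va, vb) {
  dot <- sum(va * vb)
  qa <- sum(va^2); qb <- sum(vb^2)
  if (qa == 0 || qb == 0) return(0)
  if (dot * dot >= qa * qb) return(100)
  dot / sqrt(qa * qb) * 100
}

#' Score and rank formula candidates by isotopic-pattern similarity
#'
#' Simulates each candidate's pattern, scores it against the experimental
#' spectrum with [isotopic_similarity()], and returns the candidates
#' sorted by score, descending. The sort is stable: candidates with equal
#' scores keep their input order.
#'
#' @param cands Candidate tibble from [enumerate_formulas()] (or any
#'   data frame with a `formula` column).
#' @param experimental Spectrum covering the isotopic envelope.
#' @param a Adduct used for simulation.
#' @param match_tol,tol_unit Passed to [isotopic_similarity()].
#' @param prune,merge_tol Passed to [simulate_pattern()].
#' @return The candidate tibble with an `isotopic_similarity` column,
#'   sorted by it, descending.
#' @export
rank_by_isotopic_similarity <- function(cands, experimental, a = "[M+H]+",
                                        match_tol = 5,
                                        tol_unit = c("ppm", "da"),
                                        prune = 1e-4, merge_tol = 1e-3) {
  tol_unit <- match.arg(tol_unit)
  if (nrow(cands) == 0) stop("no candidates to rank", call. = FALSE)
  scores <- purrr::map_dbl(cands$formula, function(fm) {
    pat <- simulate_pattern(fm, a, prune = prune, merge_tol = merge_tol)
    isotopic_similarity(experimental, pat, match_tol, tol_unit)
  })
  cands$isotopic_similarity <- scores
  cands[order(-scores), , drop = FALSE]
}
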
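test_that("cosine similarity: identity, disjoint support, hand example", {
  a <- spectrum(c(100, 150), c(1, 2))
  b <- spectrum(c(100, 150), c(2, 1))
  expect_equal(cosine_match(a, b, tol = 0.01), 80, tolerance = 1e-12)
  expect_identical(cosine_match(a, a), 100)
  far <- spectrum(c(300, 400), c(1, 1))
  expect_equal(cosine_match(a, far), 0)
})

test_that("cosine similarity is symmetric and never pairs a peak twice", {
  set.seed(17)
  for (trial in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    s1 <- spectrum(runif(n1, 50, 500), runif(n1, 1, 100))
    s2 <- spectrum(runif(n2, 50, 500), runif(n2, 1, 100))
    x <- cosine_match(s1, s2, tol = 5)
    y <- cosine_match(s2, s1, tol = 5)
    expect_equal(x, y, tolerance = 1e-9)
    expect_gte(x, 0); expect_lte(x, 100)
    # upper bound from one-to-one pairing: score cannot exceed the
    # cosine of fully matched sorted intensity vectors
    k <- min(n1, n2)
    ub <- sum(sort(s1$intensity, TRUE)[1:k] * sort(s2$intensity, TRUE)[1:k]) /
      (sqrt(sum(s1$intensity^2)) * sqrt(sum(s2$intensity^2))) * 100
    expect_lte(x, ub + 1e-9)
  }
})

test_that("identical spectra match at exactly 100 for any valid spectrum", {
  set.seed(4)
  for (trial in 1:20) {
    n <- sample(1:15, 1)
    s <- spectrum(sort(runif(n, 50, 800)), runif(n, 0.1, 1e5))
    expect_identical(cosine_match(s, s), 100)
  }
})

test_that("library matching returns the query itself as a perfect top hit", {
  lib <- make_fixture_library(fixture_spec(seed = 21, library_size = 12))
  q <- lib$peaks[[4]]
  hits <- match_against_library(q, lib)
  expect_gte(nrow(hits), 1)
  expect_identical(hits$id[[1]], lib$id[[4]])
  expect_identical(hits$score[[1]], 100)
})

test_that("precursor prefilter excludes out-of-window entries", {
  lib <- make_fixture_library(fixture_spec(seed = 21, library_size = 12))
  q <- spectrum(c(100, 200), c(1, 1), precursor_mz = 999.9)
  expect_equal(nrow(match_against_library(q, lib)), 0)
  q2 <- spectrum(c(100, 200), c(1, 1))
  expect_error(match_against_library(q2, lib), "precursor")
})

test_that("shuffled-peak decoys score far below the true entry", {
  spec <- fixture_spec(seed = 8, ppm_sigma = 0.5, intensity_sigma = 0.02)
  truth <- make_synthetic_spectrum("C11H15NO2", "[M+H]+", spec,
                                   mode = "msms", n_fragments = 8)
  set.seed(80)
  decoys <- purrr::map(1:5, function(k) {
    spectrum(sort(runif(nrow(truth), 50, precursor_mz(truth))),
             sample(truth$intensity),
             precursor_mz = precursor_mz(truth))
  })
  entries <- tibble::tibble(
    id = c("true", paste0("decoy", 1:5)),
    precursor_mz = precursor_mz(truth),
    peaks = c(list(truth), decoys)
  )
  lib <- spectral_library(entries)
  hits <- match_against_library(truth, lib)
  expect_identical(hits$id[[1]], "true")
  expect_gt(hits$score[[1]], 95)
  expect_lt(max(hits$score[hits$id != "true"]), 10)
})

test_that("fragment search honors min_peaks and matches a linear-scan oracle", {
  frags <- c(105.0697, 133.0647, 163.0752)
  lib <- make_fixture_library(fixture_spec(seed = 33, library_size = 20))
  hits <- search_by_fragments(frags, lib, tol = 0.01, min_peaks = 1)

  # oracle: all-pairs scan with the same unit-intensity query
  q <- spectrum(frags, rep(1, 3))
  oracle <- purrr::map_dfr(seq_len(nrow(lib)), function(i) {
    p <- lib$peaks[[i]]
    n <- sum(sapply(frags, function(z) any(abs(p$mz - z) <= 0.01)))
    tibble::tibble(id = lib$id[[i]], n_matched = n,
                   score = cosine_match(p, q, tol = 0.01))
  })
  oracle <- oracle[oracle$n_matched >= 1, ]
  oracle <- oracle[order(-oracle$score), ]
  expect_identical(hits$id, oracle$id)
  expect_equal(hits$score, oracle$score, tolerance = 1e-12)

  # unsatisfiable minimum
  none <- search_by_fragments(frags, lib, tol = 0.01, min_peaks = 4)
  expect_equal(nrow(none), 0)
})

test_that("a library entry holding all query fragments ranks first", {
  frags <- c(91.0542, 119.0491, 147.0441)
  perfect <- spectrum(frags, c(50, 80, 100), precursor_mz = 200)
  partial <- spectrum(c(frags[1], 60.1, 70.2), c(1, 1, 1), precursor_mz = 210)
  lib <- spectral_library(tibble::tibble(
    id = c("full", "partial"),
    precursor_mz = c(200, 210),
    peaks = list(perfect, partial)
  ))
  hits <- search_by_fragments(frags, lib, tol = 0.005, min_peaks = 1)
  expect_identical(hits$id[[1]], "full")
  expect_equal(hits$n_matched[hits$id == "full"], 3L)
})
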
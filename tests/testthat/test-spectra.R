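test_that("spectrum construction sorts peaks and validates inputs", {
  s <- spectrum(c(150, 100, 120), c(1, 2, 3))
  expect_identical(s$mz, c(100, 120, 150))
  expect_identical(s$intensity, c(2, 3, 1))
  expect_error(spectrum(numeric(), numeric()), "at least one peak")
  expect_error(spectrum(c(100, -5), c(1, 1)), "positive")
  expect_error(spectrum(c(100, 110), c(1, -1)), "non-negative")
  expect_error(spectrum(c(100, 110), c(1, Inf)), "finite")
})

test_that("pick_peak returns the most intense in-window peak", {
  s <- spectrum(c(194.1170, 194.1175, 200.0), c(50, 100, 999))
  pk <- pick_peak(s, 194.1173, tol_ppm = 10)
  expect_equal(pk$mz, 194.1175)
  expect_equal(pk$intensity, 100)
  # intensity tie: closer m/z wins
  s2 <- spectrum(c(100.0000, 100.0008), c(10, 10))
  expect_equal(pick_peak(s2, 100.0001, tol_ppm = 10)$mz, 100.0000)
  expect_error(pick_peak(s, 300, tol_ppm = 5), "no peak")
})

test_that("the case-study fragments are assigned to known cations", {
  res <- assign_fragments("C11H15NO2", "[M+H]+",
                          c(105.0697, 133.0647, 163.0752), tol_ppm = 5)
  expect_equal(res$percent_assigned, 100)
  expect_true(all(res$assignments$assigned))
  expect_true("C8H9" %in% res$assignments$matches[[1]]$formula)
  expect_true("C9H9O" %in% res$assignments$matches[[2]]$formula)
  expect_true("C10H11O2" %in% res$assignments$matches[[3]]$formula)
})

test_that("the whole ionized composition assigns itself", {
  mz <- ion_mz("C6H12O6", "[M+H]+")
  res <- assign_fragments("C6H12O6", "[M+H]+", mz, tol_ppm = 5)
  expect_equal(res$percent_assigned, 100)
  expect_true("C6H13O6" %in% res$assignments$matches[[1]]$formula)
})

test_that("fragments heavier than the precursor ion are unassigned", {
  res <- assign_fragments("C6H12O6", "[M+H]+", 500.0, tol_ppm = 5)
  expect_equal(res$percent_assigned, 0)
  expect_false(any(res$assignments$assigned))
  expect_error(assign_fragments("C6H12O6", "[M+H]+", numeric()), "fragments")
})

test_that("assignment percentage is count-based and order-invariant", {
  fr <- c(105.0697, 133.0647, 163.0752, 500.0)
  a <- assign_fragments("C11H15NO2", "[M+H]+", fr, 5)
  b <- assign_fragments("C11H15NO2", "[M+H]+", rev(fr), 5)
  expect_equal(a$percent_assigned, 75)
  expect_equal(b$percent_assigned, 75)
  expect_setequal(a$assignments$fragment_mz, b$assignments$fragment_mz)
})

test_that("every reported subformula obeys the elementwise bound and ppm", {
  set.seed(31)
  for (trial in 1:12) {
    prec <- random_formula(max_atoms = 16)
    ion <- formula_add(prec, c(H = 1))
    # one guaranteed-true fragment (a strict subcomposition of the ion)
    sub <- unclass(ion)
    drop_el <- sample(names(sub), 1)
    sub[drop_el] <- sub[drop_el] - 1L
    sub <- sub[sub > 0]
    true_frag <- monoisotopic_mass(mol_formula(sub)) - ELECTRON_MASS
    frags <- c(true_frag, runif(2, 40, max(41, ion_mz(prec, "[M+H]+") - 1)))
    res <- assign_fragments(prec, "[M+H]+", frags, tol_ppm = 200)
    expect_true(res$assignments$assigned[[1]])
    for (i in seq_len(nrow(res$assignments))) {
      m <- res$assignments$matches[[i]]
      for (k in seq_len(nrow(m))) {
        g <- unclass(parse_formula(m$formula[[k]]))
        expect_true(all(names(g) %in% names(ion)))
        expect_true(all(g <= unclass(ion)[names(g)]))
        expect_lte(abs(m$ppm_error[[k]]), 200 + 1e-9)
        # re-verify the reported ion m/z from the subformula
        expect_equal(m$mz[[k]],
                     monoisotopic_mass(parse_formula(m$formula[[k]])) -
                       ELECTRON_MASS,
                     tolerance = 1e-9)
      }
    }
  }
})
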
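# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals: plain
# nested expansion and exhaustive enumeration.

# all compositions within the ranges whose ion m/z is within tol_ppm of
# observed_mz, by expanding the full cross product of counts
oracle_enumerate <- function(observed_mz, adduct_name, tol_ppm, ranges_df) {
  el <- element_table()
  masses <- stats::setNames(el$monoisotopic_mass, el$element)
  grids <- lapply(seq_len(nrow(ranges_df)), function(i) {
    ranges_df$min[i]:ranges_df$max[i]
  })
  names(grids) <- ranges_df$element
  grid <- do.call(expand.grid, grids)
  neutral <- as.matrix(grid) %*% masses[ranges_df$element]
  a <- adduct(adduct_name)
  delta_mass <- if (length(a$delta) == 0) 0 else
    sum(a$delta * masses[names(a$delta)])
  ion <- (neutral + delta_mass - a$charge * ELECTRON_MASS) / abs(a$charge)
  # the adduct delta must leave no negative atom count
  feasible <- rep(TRUE, nrow(grid))
  for (e in names(a$delta[a$delta < 0])) {
    have <- if (e %in% names(grid)) grid[[e]] else 0L
    feasible <- feasible & (have + a$delta[[e]] >= 0)
  }
  hit <- feasible & abs((observed_mz - ion) / ion * 1e6) <= tol_ppm
  rows <- grid[hit, , drop = FALSE]
  out <- apply(rows, 1, function(r) {
    r <- r[r > 0]
    if (length(r) == 0) return("")
    formula_string(mol_formula(r))
  })
  sort(unname(out[nzchar(out)]))
}

# exhaustive isotopologue enumeration for a small neutral formula:
# every combination of one isotope choice per atom, then abundance-weighted
# centroiding of species closer than merge_tol (same merge definition as
# the simulator, re-stated independently)
oracle_isotopologues <- function(f, merge_tol = 1e-4) {
  f <- as_mol_formula(f)
  el <- element_table()
  iso <- stats::setNames(el$isotopes, el$element)
  atoms <- rep(names(f), times = as.integer(f))
  choices <- lapply(atoms, function(e) seq_len(nrow(iso[[e]])))
  grid <- do.call(expand.grid, choices)
  mass <- numeric(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (k in seq_along(atoms)) {
    tab <- iso[[atoms[k]]]
    mass <- mass + tab$mass[grid[[k]]]
    prob <- prob * tab$abundance[grid[[k]]]
  }
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  cluster <- cumsum(c(1, diff(mass) > merge_tol))
  data.frame(
    mass = as.numeric(tapply(mass * prob, cluster, sum) /
                        tapply(prob, cluster, sum)),
    prob = as.numeric(tapply(prob, cluster, sum))
  )
}

# a random valid small formula drawn from common elements
random_formula <- function(max_atoms = 20) {
  els <- c("C", "H", "N", "O", "S", "Cl")
  n_el <- sample(2:4, 1)
  pick <- sample(els, n_el)
  counts <- sapply(pick, function(e) sample.int(max_atoms %/% n_el, 1))
  mol_formula(counts)
}
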
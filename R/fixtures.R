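# run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic-data generators
#'
#' One object controls every generator so a single seed makes all
#' synthetic inputs reproducible: with the seed fixed, generator output
#' is byte-identical across runs. Noise defaults are typical of a
#' well-calibrated Orbitrap-class instrument: 1 ppm m/z jitter and 5%
#' relative intensity noise.
#'
#' @param seed Integer random seed; the only source of randomness.
#' @param ppm_sigma Gaussian m/z jitter, in ppm (>= 0).
#' @param intensity_sigma Relative Gaussian intensity noise (>= 0).
#' @param n_decoys Number of random decoy peaks added to MS1 fixtures.
#' @param library_size Entries in a fixture spectral library.
#' @param store_records,store_unique Record and unique-structure counts
#'   for fixture compound stores.
#' @param tax_breadth Lineages per rank level in fixture taxonomies.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, ppm_sigma = 1, intensity_sigma = 0.05,
                         n_decoys = 0L, library_size = 20L,
                         store_records = 50L, store_unique = 30L,
                         tax_breadth = 3L) {
  stopifnot(ppm_sigma >= 0, intensity_sigma >= 0, n_decoys >= 0,
            library_size >= 0, store_unique >= 1,
            store_records >= store_unique)
  structure(list(seed = as.integer(seed), ppm_sigma = ppm_sigma,
                 intensity_sigma = intensity_sigma,
                 n_decoys = as.integer(n_decoys),
                 library_size = as.integer(library_size),
                 store_records = as.integer(store_records),
                 store_unique = as.integer(store_unique),
                 tax_breadth = as.integer(tax_breadth)),
            class = "fixture_spec")
}

#' Generate a synthetic spectrum for a known formula
#'
#' MS1 mode emulates a survey scan of the ionized formula: the simulated
#' isotope pattern with Gaussian ppm jitter on m/z, relative Gaussian
#' noise on intensities, and optional random decoy peaks. MS/MS mode
#' emulates a fragment scan: peaks at the exact single-charge ion m/z of
#' a seeded random subset of subformulas of the ionized composition
#' (plus any m/z in `include_mz`, realized as the nearest subformula
#' ion), with the same noise model. What it does not emulate: peak-shape
#' effects, detector saturation, chimeric precursors, or real
#' fragmentation chemistry — subformulas are sampled combinatorially,
#' not by bond breaking.
#'
#' @param f Neutral formula.
#' @param a Adduct.
#' @param spec A [fixture_spec()].
#' @param mode `"ms1"` or `"msms"`.
#' @param n_fragments Target number of fragment peaks in MS/MS mode.
#' @param include_mz Fragment m/z values that must be present (MS/MS
#'   mode); each is realized as the subformula ion closest to it.
#' @return A [spectrum()]; deterministic given `spec$seed`.
#' @export
make_synthetic_spectrum <- function(f, a = "[M+H]+", spec = fixture_spec(),
                                    mode = c("ms1", "msms"),
                                    n_fragments = 8L, include_mz = NULL) {
  mode <- match.arg(mode)
  f <- as_mol_formula(f)
  a <- adduct(a)
  .with_seed(spec$seed, {
    if (mode == "ms1") {
      pat <- simulate_pattern(f, a)
      mz <- pat$mz * (1 + stats::rnorm(nrow(pat), 0, spec$ppm_sigma) * 1e-6)
      int <- pat$abundance *
        pmax(0.01, 1 + stats::rnorm(nrow(pat), 0, spec$intensity_sigma))
      if (spec$n_decoys > 0) {
        span <- range(pat$mz)
        mz <- c(mz, stats::runif(spec$n_decoys, span[1] - 5, span[2] + 5))
        int <- c(int, stats::runif(spec$n_decoys, 0, 0.2 * max(int)))
      }
      spectrum(mz, int, precursor_mz = ion_mz(f, a), precursor_adduct = a$name,
               metadata = list(title = paste0(formula_string(f), " MS1")))
    } else {
      ion <- formula_add(f, a$delta)
      esign <- if (a$charge >= 0) 1 else -1
      subs <- .random_subformulas(ion, n_fragments)
      mzs <- purrr::map_dbl(subs, monoisotopic_mass) - esign * ELECTRON_MASS
      if (!is.null(include_mz)) {
        forced <- purrr::map_dbl(include_mz, function(target) {
          all_subs <- .enumerate_mass_window(
            target + esign * ELECTRON_MASS - 0.6,
            target + esign * ELECTRON_MASS + 0.6,
            element_ranges(tibble::tibble(element = names(ion), min = 0L,
                                          max = as.integer(ion)))
          )
          all_subs <- purrr::keep(all_subs, ~ sum(.x) > 0)
          if (length(all_subs) == 0) {
            stop(sprintf("no subformula ion near %.4f", target), call. = FALSE)
          }
          cand <- purrr::map_dbl(all_subs, ~ monoisotopic_mass(mol_formula(.x)))
          cand[which.min(abs(cand - esign * ELECTRON_MASS - target))] -
            esign * ELECTRON_MASS
        })
        mzs <- c(mzs, forced)
      }
      mzs <- sort(unique(mzs))
      mzs <- mzs * (1 + stats::rnorm(length(mzs), 0, spec$ppm_sigma) * 1e-6)
      int <- stats::runif(length(mzs), 5, 100)
      spectrum(mzs, int, precursor_mz = ion_mz(f, a),
               precursor_adduct = a$name,
               metadata = list(title = paste0(formula_string(f), " MSMS"),
                               activation = "HCD"))
    }
  })
}

# seeded random non-empty, non-full subcompositions of an ion composition
.random_subformulas <- function(ion, n) {
  total <- as.integer(ion)
  out <- list()
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    cand <- stats::setNames(
      as.integer(floor(stats::runif(length(total), 0, total + 1))),
      names(ion)
    )
    s <- sum(cand)
    if (s == 0L || s == sum(total)) next
    # keep fragments in a plausible mass region (above ~40 Da)
    fm <- mol_formula(cand)
    if (monoisotopic_mass(fm) < 40) next
    out[[paste(cand, collapse = ",")]] <- fm
  }
  unname(out)
}

#' Generate a synthetic spectral library
#'
#' Builds `spec$library_size` annotated MS/MS entries from an internal
#' pool of plausible small-molecule formulas (repeating the pool with
#' distinct adduct-retaining ids when the requested size exceeds it).
#' Entry k is generated with seed `spec$seed + k`, so the library is
#' deterministic as a whole.
#'
#' @param spec A [fixture_spec()].
#' @param formulas Optional character vector overriding the formula pool.
#' @return A [spectral_library()].
#' @export
make_fixture_library <- function(spec = fixture_spec(), formulas = NULL) {
  pool <- formulas %||% c(
    "C11H15NO2", "C8H10N4O2", "C9H8O4", "C10H12N2O", "C16H18N2O4S",
    "C7H6O2", "C6H12O6", "C9H11NO2", "C10H14N2", "C12H22O11",
    "C5H9NO4", "C8H9NO2", "C13H18O2", "C14H18N2O5", "C6H8O7",
    "C10H13N5O4", "C7H8N4O2", "C9H13NO3", "C11H12N2O2", "C6H5NO2"
  )
  n <- spec$library_size
  fms <- rep_len(pool, n)
  entries <- purrr::map(seq_len(n), function(k) {
    sp <- fixture_spec(seed = spec$seed + k, ppm_sigma = spec$ppm_sigma,
                       intensity_sigma = spec$intensity_sigma)
    s <- make_synthetic_spectrum(fms[[k]], "[M+H]+", sp, mode = "msms",
                                 n_fragments = 6L)
    tibble::tibble(
      id = sprintf("lib_%03d", k),
      name = sprintf("fixture compound %d (%s)", k, fms[[k]]),
      formula = fms[[k]],
      precursor_mz = precursor_mz(s),
      source = c("massbank", "gnps")[[k %% 2 + 1]],
      peaks = list(s)
    )
  })
  spectral_library(dplyr::bind_rows(entries))
}

# chiral SMILES templates used to exercise stereo-insensitive grouping;
# each has one stereocenter written with '@@'
.chiral_templates <- c(
  "C[C@@H](N)C(=O)O", "C[C@@H](O)CC", "C[C@@H](N)CC(=O)O",
  "OC[C@@H](O)CO", "C[C@@H](Cl)C(=O)O", "N[C@@H](CO)C(=O)O"
)

# achiral SMILES pool for fixture stores (all neutral, single component)
.achiral_pool <- function(n) {
  groups <- c("O", "N", "C(=O)O", "S", "OC", "C#N", "C(=O)N", "Cl")
  out <- character(0)
  k <- 1L
  while (length(out) < n) {
    for (g in groups) {
      out <- c(out, paste0(strrep("C", k), g))
      if (length(out) >= n) break
    }
    k <- k + 1L
  }
  out[seq_len(n)]
}

#' Generate a synthetic per-source compound record dump
#'
#' Emits `spec$store_records` records over `spec$store_unique` unique
#' structures, so aggregation has genuine duplicates to merge. A few
#' structures carry stereocenters and are emitted in both enantiomeric
#' notations from different sources — these must collapse to one
#' document. Records are spread over sources including natural-product
#' databases (`lotus`, `coconut`), and carry bioassay outcomes,
#' lineages drawn from the fixture taxonomy, and literature references.
#'
#' @param spec A [fixture_spec()].
#' @return A list of record lists (ready for [aggregate_records()] or
#'   [write_records()]).
#' @export
make_fixture_records <- function(spec = fixture_spec()) {
  .with_seed(spec$seed, {
    n_chiral <- min(length(.chiral_templates), max(0L, spec$store_unique %/% 5L))
    chiral <- .chiral_templates[seq_len(n_chiral)]
    achiral <- .achiral_pool(spec$store_unique - n_chiral)
    base <- c(chiral, achiral)
    sources <- c("pubchem", "chembl", "lotus", "coconut", "massbank")
    lineages <- list(
      list(Genus = "Coffea", Species = "Coffea arabica"),
      list(Family = "Rubiaceae", Genus = "Coffea"),
      list(Species = "Unknownus inventus"),
      list(Kingdom = "Viridiplantae", Phylum = "Streptophyta")
    )
    # every unique structure appears at least once; extras are duplicates
    idx <- c(seq_len(spec$store_unique),
             sample.int(spec$store_unique,
                        spec$store_records - spec$store_unique,
                        replace = TRUE))
    idx <- sample(idx)  # shuffle so duplicates are interleaved
    purrr::map(seq_along(idx), function(k) {
      i <- idx[[k]]
      smi <- base[[i]]
      # chiral structures: half the duplicate emissions flip the center
      if (grepl("@@", smi, fixed = TRUE) && stats::runif(1) < 0.5) {
        smi <- sub("@@", "@", smi, fixed = TRUE)
      }
      src <- sample(sources, 1)
      acts <- if (stats::runif(1) < 0.4) {
        list(list(assay = sprintf("assay_%02d", sample.int(20, 1)),
                  active = stats::runif(1) < 0.6))
      } else list()
      taxa <- if (stats::runif(1) < 0.5) {
        list(lineages[[sample.int(length(lineages), 1)]])
      } else list()
      refs <- if (stats::runif(1) < 0.5) {
        as.list(sprintf("PMID:%07d", sample.int(9999999, sample.int(2, 1))))
      } else list()
      list(structure = smi, source = src,
           source_id = sprintf("%s_%04d", src, k),
           name = sprintf("fixture_%03d", i),
           activities = acts, taxonomies = taxa, references = refs)
    })
  })
}

#' Generate a synthetic eight-rank taxonomy reference
#'
#' Builds a complete reference tree with `spec$tax_breadth` lineages,
#' each spanning all eight harmonized ranks below a shared root, with
#' systematic synthetic names (`Genus_2`, ...). A real coffee lineage
#' (Eukaryota ... Coffea arabica) is always included so that fixtures
#' exercising reconstruction from a deep match have a stable target.
#'
#' @param spec A [fixture_spec()].
#' @return A [taxonomy_reference()].
#' @export
make_fixture_taxonomy <- function(spec = fixture_spec()) {
  ranks <- tolower(taxonomy_ranks())
  nodes <- list(tibble::tibble(id = 1L, parent = 1L, rank = "no rank"))
  names_ <- list(tibble::tibble(id = 1L, name = "root"))
  next_id <- 2L
  add_lineage <- function(names8) {
    parent <- 1L
    for (d in seq_along(ranks)) {
      id <- next_id
      next_id <<- next_id + 1L
      nodes[[length(nodes) + 1]] <<- tibble::tibble(
        id = id, parent = parent, rank = ranks[[d]]
      )
      names_[[length(names_) + 1]] <<- tibble::tibble(
        id = id, name = names8[[d]]
      )
      parent <- id
    }
  }
  add_lineage(c("Eukaryota", "Viridiplantae", "Streptophyta",
                "Magnoliopsida", "Gentianales", "Rubiaceae", "Coffea",
                "Coffea arabica"))
  for (b in seq_len(spec$tax_breadth)) {
    add_lineage(sprintf("%s_%d", taxonomy_ranks(), b))
  }
  taxonomy_reference(dplyr::bind_rows(nodes), dplyr::bind_rows(names_))
}

#' Generate a synthetic aggregated compound store
#'
#' Convenience wrapper: [make_fixture_records()] piped through
#' [aggregate_records()] with the fixture taxonomy and the fixture
#' natural-product source list (`lotus`, `coconut`).
#'
#' @param spec A [fixture_spec()].
#' @return A [compound_store()].
#' @export
make_fixture_store <- function(spec = fixture_spec()) {
  aggregate_records(make_fixture_records(spec),
                    tax_ref = make_fixture_taxonomy(spec),
                    np_sources = c("lotus", "coconut"))
}
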
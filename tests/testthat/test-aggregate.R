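test_that("merging a single record is the identity up to document shape", {
  recs <- list(list(structure = "CCO", source = "pubchem",
                    source_id = "x1", references = list("PMID:1")))
  st <- aggregate_records(recs)
  expect_equal(nrow(st), 1)
  expect_identical(st$formula[[1]], "C2H6O")
  expect_equal(st$monoisotopic_mass[[1]], monoisotopic_mass("C2H6O"),
               tolerance = 1e-9)
  expect_identical(st$references[[1]], "PMID:1")
  expect_equal(nrow(st$sources[[1]]), 1)
})

test_that("records sharing a key merge into one labeled document", {
  recs <- list(
    list(structure = "C[C@@H](N)C(=O)O", source = "lotus", source_id = "l1",
         taxonomies = list(list(Genus = "Coffea"))),
    list(structure = "C[C@H](N)C(=O)O", source = "chembl", source_id = "c1",
         activities = list(list(assay = "assay_01", active = TRUE)))
  )
  st <- aggregate_records(recs, np_sources = "lotus")
  expect_equal(nrow(st), 1)
  expect_setequal(st$labels[[1]], c("natural-product", "bioactive"))
  expect_equal(nrow(st$sources[[1]]), 2)
})

test_that("merge order does not change the document", {
  recs <- list(
    list(structure = "CCO", source = "pubchem", source_id = "a",
         references = list("PMID:2")),
    list(structure = "CCO", source = "massbank", source_id = "b",
         activities = list(list(assay = "z", active = FALSE))),
    list(structure = "CCO", source = "lotus", source_id = "c",
         taxonomies = list(list(Family = "Rubiaceae")))
  )
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stores <- lapply(perms, function(p) {
    aggregate_records(recs[p], np_sources = "lotus")
  })
  f1 <- tempfile()
  write_store(stores[[1]], f1)
  base <- readLines(f1)
  for (k in 2:6) {
    fk <- tempfile()
    write_store(stores[[k]], fk)
    expect_identical(readLines(fk), base)
  }
})

test_that("merge is idempotent over random groupings", {
  set.seed(12)
  recs <- make_fixture_records(fixture_spec(seed = 3, store_records = 24,
                                            store_unique = 10))
  full <- aggregate_records(recs, np_sources = c("lotus", "coconut"))
  for (trial in 1:20) {
    st <- aggregate_records(sample(recs), np_sources = c("lotus", "coconut"))
    expect_identical(st$key, full$key)
    expect_identical(st$labels, full$labels)
    expect_identical(st$sources, full$sources)
  }
})

test_that("aggregation output size and degenerate inputs behave", {
  spec <- fixture_spec(seed = 5, store_records = 40, store_unique = 25)
  recs <- make_fixture_records(spec)
  st <- aggregate_records(recs)
  expect_equal(nrow(st), 25)
  expect_lte(nrow(st), length(recs))
  empty <- aggregate_records(list())
  expect_equal(nrow(empty), 0)
  # all keys distinct -> output count equals input count
  uni <- aggregate_records(make_fixture_records(
    fixture_spec(seed = 6, store_records = 10, store_unique = 10)
  ))
  expect_equal(nrow(uni), 10)
})

test_that("malformed structures are counted and skipped, not fatal", {
  recs <- list(
    list(structure = "CCO", source = "pubchem", source_id = "1"),
    list(structure = "((broken", source = "pubchem", source_id = "2"),
    list(structure = "C1CC1", source = "pubchem", source_id = "3")
  )
  st <- suppressWarnings(aggregate_records(recs))
  expect_equal(nrow(st), 2)
  expect_equal(attr(st, "skipped"), 1L)
})

test_that("mass search via the sorted index equals a linear scan", {
  st <- suppressWarnings(make_fixture_store(
    fixture_spec(seed = 44, store_records = 60, store_unique = 30)
  ))
  expect_false(is.unsorted(st$monoisotopic_mass))
  set.seed(90)
  queries <- c(st$monoisotopic_mass[sample.int(nrow(st), 10)],
               runif(10, 20, 300))
  for (q in queries) {
    got <- search_by_mass(st, q, tol_ppm = 12)
    scan <- st$key[abs((q - st$monoisotopic_mass) /
                         st$monoisotopic_mass * 1e6) <= 12]
    expect_setequal(got$key, scan)
  }
  # window edge: a query offset by twice the tolerance misses
  m <- st$monoisotopic_mass[[7]]
  off <- m * (1 + 24e-6)
  expect_false(st$key[[7]] %in% search_by_mass(st, off, tol_ppm = 12)$key)
})

test_that("the known-structure filter applies the neutral >= n rule", {
  # store with 6 neutral ethanol-formula docs and 4 of another formula
  mk <- function(smiles, n) {
    lapply(seq_len(n), function(i) {
      list(structure = smiles[[((i - 1) %% length(smiles)) + 1]],
           source = "pubchem", source_id = paste0(smiles[[1]], i))
    })
  }
  # 6 distinct C6H14O isomers and 4 distinct C4H11N isomers
  c6 <- c("CCCCCCO", "CCCCC(C)O", "CCCC(CC)O", "OCC(C)CCC",
          "OCCC(C)CC", "CCCCOCC")
  n4 <- c("CCCCN", "CCC(C)N", "CC(C)CN", "CN(C)CC")
  recs <- c(mk(c6, 6), mk(n4, 4))
  st <- aggregate_records(recs)
  cands <- tibble::tibble(
    formula = c("C6H14O", "C4H11N", "CH4"),
    counts = list(NULL, NULL, NULL),
    mz = NA_real_, ppm_error = c(0.5, -0.2, 1),
    rdbe = 0, has_known_structures = FALSE, bioactive_or_natural = FALSE
  )
  kept <- filter_known_structures(cands, st, min_structures = 5)
  expect_identical(kept$formula, "C6H14O")
  expect_true(all(kept$has_known_structures))
  # threshold boundary: 4 records is not enough at min 5, enough at 4
  kept4 <- filter_known_structures(cands, st, min_structures = 4)
  expect_identical(kept4$formula, c("C6H14O", "C4H11N"))
  # order preservation: subset keeps input order
  expect_identical(kept4$formula,
                   cands$formula[cands$formula %in% kept4$formula])
  # empty store passes nothing
  empty <- aggregate_records(list())
  expect_equal(nrow(filter_known_structures(cands, empty)), 0)
})

test_that("charged structures are excluded from the neutral count", {
  recs <- c(
    lapply(1:5, function(i) list(structure = "CCCCCCO", source = "s",
                                 source_id = paste0("n", i))),
    list(list(structure = "C[N+](C)(C)C", source = "s", source_id = "q"))
  )
  st <- aggregate_records(recs)
  expect_true(any(st$formal_charge == 1L))
  cands <- tibble::tibble(
    formula = c("C6H14O", msderep:::.inchi_formula(
      st$key[st$formal_charge == 1L])),
    counts = list(NULL, NULL), mz = NA_real_, ppm_error = 0, rdbe = 0,
    has_known_structures = FALSE, bioactive_or_natural = FALSE
  )
  kept <- filter_known_structures(cands, st, min_structures = 1)
  expect_false(any(grepl("N", kept$formula)))
})
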
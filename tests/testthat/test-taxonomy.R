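ref <- make_fixture_taxonomy(fixture_spec(seed = 1))

test_that("normalization always yields exactly the eight named ranks", {
  cases <- list(
    c(Genus = "Coffea", Species = "Coffea arabica"),
    c(Species = "Unknownus inventus"),
    c(superkingdom = "Eukaryota"),
    c(domain = "Something", family = "Else"),
    c(Family = "Rubiaceae")
  )
  for (lin in cases) {
    out <- normalize_taxonomy(lin, ref)
    expect_identical(setdiff(names(out), "provenance"), taxonomy_ranks())
    expect_equal(nrow(out), 1)
    expect_true(out$provenance %in% c("ncbi_matched", "preserved_original"))
  }
  out0 <- normalize_taxonomy(c(Genus = "Coffea"), ref = NULL)
  expect_identical(setdiff(names(out0), "provenance"), taxonomy_ranks())
})

test_that("a matched lineage is reconstructed from the reference walk", {
  out <- normalize_taxonomy(c(Genus = "Coffea", Species = "Coffea arabica"),
                            ref)
  expect_identical(out$provenance, "ncbi_matched")
  expect_identical(out$SuperKingdom, "Eukaryota")
  expect_identical(out$Kingdom, "Viridiplantae")
  expect_identical(out$Family, "Rubiaceae")
  expect_identical(out$Species, "Coffea arabica")
  expect_false(any(unlist(out[taxonomy_ranks()]) == ""))
  # no blank between two filled ranks after reconstruction
  filled <- unlist(out[taxonomy_ranks()]) != ""
  expect_true(all(diff(which(filled)) == 1))
})

test_that("matching is case-insensitive and falls back to shallower ranks", {
  out <- normalize_taxonomy(c(genus = "COFFEA", species = "Nonexistus x"),
                            ref)
  expect_identical(out$provenance, "ncbi_matched")
  expect_identical(out$Genus, "Coffea")
  # the unmatched deeper name is preserved in its own slot
  expect_identical(out$Species, "Nonexistus x")
})

test_that("unmatched lineages are preserved with blanks elsewhere", {
  out <- normalize_taxonomy(c(Species = "Unknownus inventus"), ref)
  expect_identical(out$provenance, "preserved_original")
  expect_identical(out$Species, "Unknownus inventus")
  expect_true(all(unlist(out[setdiff(taxonomy_ranks(), "Species")]) == ""))
})

test_that("a complete matched lineage is a fixed point", {
  full <- normalize_taxonomy(c(Genus = "Coffea", Species = "Coffea arabica"),
                             ref)
  again <- normalize_taxonomy(
    stats::setNames(unlist(full[taxonomy_ranks()]), taxonomy_ranks()), ref
  )
  expect_identical(unlist(again[taxonomy_ranks()]),
                   unlist(full[taxonomy_ranks()]))
})

test_that("degenerate lineages are rejected", {
  expect_error(normalize_taxonomy(c(), ref), "named")
  expect_error(normalize_taxonomy(c(NotARank = "x"), ref), "recognizable")
  expect_error(normalize_taxonomy(c(Genus = ""), ref), "recognizable")
})

test_that("taxdump files round-trip through the reader and writer", {
  dir <- tempfile()
  write_taxdump(ref, dir)
  back <- read_taxdump(dir)
  expect_identical(back$nodes, ref$nodes)
  expect_identical(back$names, ref$names)
  out1 <- normalize_taxonomy(c(Genus = "Coffea"), ref)
  out2 <- normalize_taxonomy(c(Genus = "Coffea"), back)
  expect_identical(out1, out2)
})

test_that("reference validation rejects broken trees", {
  nodes <- tibble::tibble(id = c(1L, 2L), parent = c(1L, 3L),
                          rank = c("no rank", "genus"))
  nms <- tibble::tibble(id = c(1L, 2L), name = c("root", "G"))
  expect_error(taxonomy_reference(nodes, nms), "dangling")
  nodes2 <- tibble::tibble(id = c(1L, 2L, 3L), parent = c(1L, 3L, 2L),
                           rank = c("no rank", "genus", "family"))
  nms2 <- tibble::tibble(id = 1:3, name = c("root", "G", "F"))
  expect_error(taxonomy_reference(nodes2, nms2), "cycle")
  expect_error(
    taxonomy_reference(tibble::tibble(id = 1L, parent = 1L, rank = "no rank"),
                       tibble::tibble(id = integer(), name = character())),
    "name"
  )
})
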
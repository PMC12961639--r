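Package: msderep
Title: Dereplication of Small Molecules from High-Resolution Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dereplicating small molecules from high-resolution
    mass spectrometry data against a locally aggregated compound database.
    Enumerates candidate molecular formulas for an observed m/z under
    per-element count ranges and a ppm mass tolerance, simulates isotopic
    patterns by convolution and ranks candidates by pattern similarity,
    scores MS/MS fragment consistency by subformula assignment, matches
    spectra against a local spectral library by cosine similarity, merges
    multi-source compound records under a stereochemistry- and
    tautomer-insensitive structure key, and harmonizes organism annotations
    to a fixed eight-rank taxonomy. Readers and writers for MGF, MSP and
    JSON spectra, line-delimited JSON compound dumps and NCBI-style
    taxonomy dumps are included, together with deterministic synthetic-data
    generators for spectra, compound stores and mini-taxonomies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    stringr,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (the 'obabel' executable) for structure
    canonicalization; only needed by the record-aggregation functions.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
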
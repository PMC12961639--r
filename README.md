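# msderep

Dereplication — recognizing already-known small molecules early, so that
effort goes to genuinely novel ones — is the first question asked of any
high-resolution mass spectrum: *what could this ion be, and is it already
in a database?* `msderep` implements the computational core of that
workflow in R, for mass spectrometrists and natural-product chemists who
want it scriptable, offline and testable:

- **Candidate molecular formulas.** For an observed ion at m/z *x* under
  an adduct with charge *z* and formula delta δ, every composition
  **n** = (n_C, n_H, …) inside per-element count ranges is found with

  |(x − x̂)/x̂| · 10⁶ ≤ tol, where x̂ = (Σᵢ nᵢmᵢ + m_δ − z·mₑ)/|z|,

  mᵢ the monoisotopic element masses and mₑ the electron mass —
  protonation adds 1.00727646688 Da (H minus an electron), which matters
  at single-digit ppm. The search is exhaustive (a depth-first scan with
  mass pruning, verified against brute-force enumeration), not heuristic.
- **Isotopic-pattern ranking.** Theoretical isotopologue distributions by
  convolution of per-element isotope tables; candidates are scored by the
  cosine between aligned experimental and simulated abundance vectors
  (reported as a percentage).
- **MS/MS fragment consistency.** The percentage of fragment ions that
  admit at least one subformula of the ionized precursor within
  tolerance, fragments modeled as even-electron cations.
- **Spectral library matching.** Greedy one-to-one peak pairing and
  cosine scoring against MGF/MSP/JSON libraries, with precursor
  prefiltering and fragment-set search.
- **Record aggregation.** Multi-source compound records merged under a
  stereochemistry- and tautomer-insensitive structure key (stereo-truncated
  standard InChI via Open Babel), with natural-product/bioactive labels
  and organism annotations harmonized to the eight ranks
  SuperKingdom…Species against an NCBI-style taxonomy dump.

Everything is tibble-first and pipe-friendly; deterministic synthetic-data
generators (spectra, compound stores, mini-taxonomies) make the whole
pipeline runnable and testable without any download.

## Worked example

An unknown ion is observed at m/z 194.1173 in positive mode. Enumerate
formulas under broad ranges, then rank by isotopic-pattern similarity
against a (here: synthetic) survey spectrum of the true compound,
MDMA (C₁₁H₁₅NO₂):

```r
library(msderep)
library(dplyr)

cands <- enumerate_formulas(194.1173, "[M+H]+", tol_ppm = 5,
                            ranges = default_element_ranges())
nrow(cands)
#> [1] 78

ms1 <- make_synthetic_spectrum("C11H15NO2", "[M+H]+",
         fixture_spec(seed = 7, ppm_sigma = 0.5, intensity_sigma = 0.02),
         mode = "ms1")
ranked <- rank_by_isotopic_similarity(cands, ms1, "[M+H]+")
ranked |> select(formula, ppm_error, rdbe, isotopic_similarity) |> head(3)
#> # A tibble: 3 × 4
#>   formula    ppm_error  rdbe isotopic_similarity
#>   <chr>          <dbl> <dbl>               <dbl>
#> 1 C11H15NO2     -1.31    5                 100.0
#> 2 C6H14FN4O2    -0.285   1.5                99.8
#> 3 C5H21O5S      -4.87   -4.5                99.7
```

78 compositions fit a 5 ppm window — mass accuracy alone cannot decide.
The isotopic pattern puts the true formula first (the boron-containing
alternative C₁₀H₁₆BNS, the other candidate with known structures, falls
to rank 11 at 96.9% here). MS/MS fragment consistency seals it: the three
observed fragment ions all admit subformulas of protonated C₁₁H₁₅NO₂
(C₈H₉⁺, C₉H₉O⁺, C₁₀H₁₁O₂⁺):

```r
assign_fragments("C11H15NO2", "[M+H]+",
                 c(105.0697, 133.0647, 163.0752), tol_ppm = 5)$percent_assigned
#> [1] 100
```

A thin command-line wrapper over the same functions ships in
`inst/cli/msderep.R` (subcommands `formulas`, `similarity`, `fragments`,
`match`, `dbsearch`, `aggregate`, `taxnorm`, `fixtures`), emitting JSON
or tab-delimited tables.

## Scope

The package is a local, offline analysis core: no live database
synchronization, no web service, and no bond-breaking in-silico
fragmentation. Spectra are centroided; profile data and charge states
beyond |z| = 1 are out of scope. The tautomer treatment of the structure
key is the standard-InChI mobile-hydrogen one — see the methods vignette
(`vignettes/msderep-methods.Rmd`) for the full model description,
parameter defaults and limitations.
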
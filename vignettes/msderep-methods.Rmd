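---
title: "Methods: formula enumeration, isotope simulation, spectral matching and record aggregation in msderep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formula enumeration, isotope simulation, spectral matching and record aggregation in msderep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msderep` answers the dereplication question for high-resolution mass
spectra of small molecules: given an accurate m/z, optionally an MS/MS
spectrum, and a local compound database, which already-known compounds
could this be? This vignette is the package's own account of the models
and procedures behind each step, the parameters that matter, and where
the boundaries of validity lie.

```{r setup}
library(msderep)
```

## Ion mass arithmetic

All mass comparisons go through one convention. A neutral molecule M
ionized under an adduct with formula delta δ (e.g. +H for `[M+H]+`) and
charge z is observed at

$$ m/z \;=\; \frac{m(M + \delta) - z\,m_e}{|z|}, $$

with $m_e = 0.000548580$ Da the electron mass. Protonation therefore
adds the *proton* mass 1.00727646688 Da, not the hydrogen-atom mass
1.00782503 Da. The 0.55 mDa difference is 2.8 ppm at m/z 194 — larger
than the mass accuracy of a modern Orbitrap — so conflating the two
changes which formulas fall inside a 5 ppm window. Mass error is always
computed against the theoretical value, signed:
$\mathrm{ppm} = (x_\mathrm{obs} - \hat{x})/\hat{x} \cdot 10^6$;
filters compare $|\mathrm{ppm}|$ to the tolerance.

Monoisotopic element masses, isotope masses and abundances are embedded
constants from the standard IUPAC/NIST tables, covering C, H, N, O, S,
P, F, Cl, Br, I, B, Si, Na and K. The adduct registry ships
`[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+NH4]+`, `[M]+`, `[M-H]-` and
`[M+Cl]-`; additional adducts are user-definable through a YAML
configuration file (`read_config()`), since deployed instruments see
more ionization types than any fixed list anticipates. Charge states
$|z| > 1$ are accepted by the arithmetic but untested territory for the
enumeration defaults, and isotopically labeled elements are not
modeled.

## Formula enumeration

`enumerate_formulas()` must be *complete*: exactly the set of
compositions inside the per-element count ranges whose ion m/z falls in
the tolerance window. The implementation is a depth-first scan over
elements in descending-mass order. A branch is pruned as soon as the
running mass plus the least (greatest) mass still contributable by the
remaining elements overshoots (undershoots) the window — a pure
feasibility bound, so no solution can be lost. The lightest element is
never looped over: its admissible counts are solved directly from the
residual mass window, which is what keeps hydrogen-rich searches cheap
(the default ranges allow up to 200 H). Completeness is not taken on
faith: the test suite checks set equality against brute-force
cross-product enumeration on 260 randomized small-range queries
(cross products up to $10^5$ compositions, elements drawn from
C/H/N/O/S/F/Cl/Br/B/Na, several adducts and tolerances).

Two deliberate non-filters:

- **No chemical-plausibility screen.** Ring-plus-double-bond
  equivalents, $\mathrm{RDBE} = 1 + \sum_i n_i (v_i - 2)/2$ over
  standard valences, are reported as an annotation only. Broad
  screening lists legitimately contain exotic compositions (boron
  species, half-integer RDBE radical counts), and silently dropping
  them would bias exactly the unknown-identification use case the tool
  exists for. Downstream evidence — isotopic pattern, fragments, known
  structures — does the discriminating.
- **No default ordering by plausibility.** Results are sorted by
  $|\mathrm{ppm}|$ ascending with ties broken by formula text, a
  deterministic, assumption-free order.

The degenerate cases are defined rather than accidental: all-zero
ranges yield an empty table (not an error), a non-positive tolerance is
an error, and adducts that remove atoms (e.g. `[M-H]-`) tighten the
effective minimum counts so no emitted composition would need negative
atoms.

## Isotopic patterns and similarity

`simulate_pattern()` computes the isotopologue distribution of the ion
by convolution: each element's single-atom isotope distribution is
raised to its atom count (binary exponentiation of the convolution),
and element results are convolved together. Isotopologues closer than
`merge_tol` (default $10^{-3}$ Da — unresolvable at typical resolving
powers) are merged into abundance-weighted centroids. After
normalization to a base peak of 100, species below `prune`
(default $10^{-4}$ relative) are discarded. An absolute probability
floor of $10^{-12}$ inside the convolution keeps intermediate products
small; it is far below any abundance that could survive final pruning
and independent of the user-facing threshold, so lowering `prune` only
ever adds peaks. Correctness is again checked against an independent
oracle: exhaustive enumeration over every per-atom isotope choice for
formulas up to 8 atoms, agreeing within $10^{-9}$ relative abundance
and $10^{-7}$ Da.

`isotopic_similarity()` aligns pattern peaks to experimental peaks
one-to-one, closest m/z distance first, within `match_tol` (default
5 ppm, consistent with the enumeration accuracy), and scores the cosine
of the aligned abundance vectors × 100. Unmatched peaks on either side
contribute zeros, so both missing and spurious peaks cost score
symmetrically; the score is invariant under uniform intensity scaling
of the experimental spectrum. Cosine on aligned vectors is the
package's documented choice of similarity functional — percentage
agreement with other tools' isotopic-similarity scores is not implied,
only the ordering behavior that the tests pin down (the true formula's
pattern scores 100 against its own noise-free spectrum, and first
against realistically noisy ones).

## MS/MS fragment consistency and library matching

`assign_fragments()` treats fragments as even-electron cations drawn
from the protonated composition: a fragment at m/z $x$ is *assigned* if
some subformula $g$ with $0 \le g \le M{+}\delta$ element-wise
satisfies $|m(g) - m_e - x| \le$ tol (signs flip for negative mode).
The consistency score is the *count* fraction of assigned fragments, as
a percentage — intensity plays no role, because the question is
elemental consistency, not abundance modeling. The subformula search
reuses the pruned enumeration engine with per-element maxima set by the
precursor composition. This is deliberately not in-silico
fragmentation: no bonds are broken, no fragmentation chemistry is
scored, so the measure is permissive by construction (a fragment can be
elementally consistent yet chemically implausible).

`cosine_match()` pairs peaks of two spectra one-to-one within a Da
tolerance (default 0.01 Da), greedily by descending intensity product
with ties to lower m/z, and scores
$100 \cdot \sum I_a I_b / (\lVert I_a\rVert\,\lVert I_b\rVert)$ with
norms over *all* peaks. Greedy-by-product is deterministic and
order-independent, and the one-to-one constraint prevents a single
intense peak from absorbing several partners. Intensities are used raw
by default; square-root weighting is available (`sqrt_intensity =
TRUE`) but off, since the default should add no hidden transformation.
One numerical subtlety: paired contributions and the norms are summed
in sorted order, so a spectrum matched against itself accumulates
numerator and denominator from identical multisets and returns exactly
100 rather than 100 minus a rounding ulp.

`match_against_library()` prefilters candidates by a precursor window
(default 10 ppm) before cosine ranking; `search_by_fragments()` matches
a fragment m/z set (unit intensities) against entries, requiring at
least `min_peaks` hits. Libraries are tibbles sorted by precursor m/z;
entries keep their annotations so hits support substructure-frequency
inspection downstream.

## Structure keys and record aggregation

Merging compound records across source databases requires an identity
that ignores how a depositor happened to draw the molecule. The
`no_stereo_tautomer_id()` key is the standard InChI of the structure
with the stereochemical layers truncated, computed through Open Babel.
This collapses enantiomers, diastereomers and undefined-stereo
drawings, and tautomers related by the standard InChI
mobile-hydrogen treatment (e.g. 2-hydroxypyridine/2-pyridone). It is an
approximation: tautomer families outside the mobile-H rules — classic
keto–enol shifts over carbon among them — remain distinct keys. The key
*is* the truncated InChI string; being deterministic and collision-free
it needs no further hashing, and the formula, formal charge (q and p
layers) and monoisotopic mass of a document are all derived from it, so
a document can never disagree with its own key. Multi-component
structures (salts, mixtures — SMILES containing `.`) are rejected at
parse, and unparseable structures are skipped with a warning and a
count rather than aborting an aggregation run.

`aggregate_records()` groups per-source records by key and merges each
group: source entries deduplicated by (source, id), activities,
taxonomies, labels and references set-unioned under canonical sorts.
Every collection being canonically ordered makes the merge associative
and permutation-invariant, which the tests verify over a hundred random
input shufflings — byte-identical serialized stores. Labels are
attached during aggregation: `natural-product` when any contributing
source is on the user-supplied natural-product source list, `bioactive`
when any linked assay has a positive outcome flag. The
known-structure candidate filter (`filter_known_structures()`) keeps
formulas backed by at least 5 *neutral* documents (formal charge zero)
by default, mirroring the screening convention of requiring several
independently deposited neutral structures before a formula is taken
seriously.

## Taxonomy normalization

Organism annotations arrive at wildly different depths and vocabularies.
`normalize_taxonomy()` maps every lineage onto exactly eight ranks —
SuperKingdom, Kingdom, Phylum, Class, Order, Family, Genus, Species —
with rank-name synonyms (`domain`, `division`, …) folded by a fixed
alias table. The deepest provided name is matched against the reference
(exact, case-insensitive, preferring nodes whose reference rank agrees
with the provided one), falling back to the next-deepest name on
failure; "deepest first" because deeper taxa are more specific and less
homonym-prone. On a match, the full lineage is reconstructed by walking
the reference tree to the root; provided names at ranks the reference
walk does not fill are kept. Without any match, the provided names are
placed into their slots and the remaining levels stay blank — original
information is preserved, never discarded. The output always has all
eight slots, so downstream consumers can rely on the shape without
checking provenance (a `provenance` flag still records
`ncbi_matched` vs `preserved_original`). The reference is an NCBI-style
dump (`nodes.dmp`/`names.dmp`, scientific names only), validated for a
single root and acyclic parent links on construction.

## Synthetic data: what it does and does not show

The generators in `fixture_spec()` exist so every pipeline stage can be
exercised offline and deterministically — all randomness flows from the
one seed, and fixed-seed output is byte-identical.

- **MS1 fixtures** are simulated isotope patterns with Gaussian m/z
  jitter (default σ = 1 ppm) and relative intensity noise (default
  σ = 5%) — typical figures for a well-calibrated Orbitrap-class
  instrument — plus optional uniform decoy peaks.
- **MS/MS fixtures** place peaks at exact subformula-cation m/z values
  of the precursor composition (a seeded random subset, above 40 Da,
  with requested fragments realized as the nearest subformula ion),
  under the same noise model.
- **Record dumps** emit a configurable number of records over a smaller
  number of unique structures, including enantiomer pairs emitted in
  both notations from different sources, so key-collapsing is genuinely
  exercised; sources include natural-product databases, and records
  carry assays, lineages and references.
- **Taxonomy fixtures** are complete eight-rank trees plus one real
  coffee lineage as a stable deep-match target.

What passing against these fixtures shows: the arithmetic, search
completeness, scoring conventions, merge semantics and round-trips are
correct. What it does not show: performance on real spectra. Real data
bring peak-shape artifacts, detector saturation, chimeric precursors,
electronic noise structure and real fragmentation chemistry, none of
which the generators model. The self-consistency loop (true formula
recovered at similarity 100 from its own noise-free spectrum, 100%
fragment assignment from its own subformula peaks, first rank among
equal-nominal-mass decoys in ≥95% of noisy trials) is a necessary
correctness bar, not a field-performance claim.

## Problem sizes and runtime choices

The test suite runs the broad-range enumeration (ranges spanning a
$2.5\times10^{10}$-composition box) in well under a second thanks to
mass pruning; oracle-equivalence checks use 260 randomized queries
capped at $3\times10^4$–$10^5$ brute-force compositions each; the
self-consistency loop runs 50 random formulas; aggregation determinism
is checked over 100 shuffled 50-record dumps. These sizes were chosen
to exercise each code path thoroughly while keeping the full suite in
the minutes range on a single CPU.

## Known limitations

- Centroided spectra only; no profile-mode peak shapes, no
  resolution-dependent coalescence beyond the centroid merge tolerance.
- Fragment consistency is elemental, not structural: it cannot
  penalize chemically impossible but elementally valid subformulas.
- The isotopic-similarity percentage is the package's cosine
  convention; scores are comparable within the package, not across
  tools with undocumented metrics.
- Tautomer insensitivity of the structure key is bounded by the
  standard InChI mobile-H rules.
- Multiply charged ions and isotopically labeled compounds are out of
  scope; average (as opposed to monoisotopic) masses are not computed.
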
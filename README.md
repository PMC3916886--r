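# chemcollate

Compound databases that map small molecules to protein targets — medicinal
chemistry corpora, drug references, metabolome resources, target registries —
are routinely merged and cross-referenced, yet each curates structures and
target mappings by its own rules. Deciding what two releases, or two sources,
actually have *in common* requires a notion of chemical identity that is
explicit about how much it forgives: are a drug and its sodium salt the same
compound? Its deuterated analogue? The other tautomer drawing? The
unspecified-stereo version of it?

`chemcollate` is an R toolkit for such cross-database and cross-release
comparisons. It implements a graded structure-normalization cascade and
hashed identity keys at three sensitivity levels, and the comparison
statistics built on top of them, plus a parallel toolkit for UniProt
accession sets.

## The identity model

Every record parsed from an SD file is a colored graph (elements, formal
charges, isotope mass numbers, implicit-H counts; bond orders; wedge marks
and 2D coordinates for stereo). A base normalization first fixes drawing
variance: explicit hydrogens are folded in, a documented functional-group
transform table rewrites hypervalent nitro/azide/diazo and charge-separated
sulfoxide drawings, and charged resonance forms are canonicalized. From the
normalized graph, canonical serializations are hashed (128-bit digest,
27-character base-32 key) at three levels:

| level | sensitive to fragments | charges | isotopes | tautomer | stereo |
|---------|:---:|:---:|:---:|:---:|:---:|
| `ficts` (sensitive) | yes | yes | yes | yes | yes |
| `ficus` (tautomer-invariant) | yes | yes | yes | **no** | yes |
| `uuuuu` (skeleton) | **no** | **no** | **no** | **no** | **no** |

so that `uniques(ficts) >= uniques(ficus) >= uniques(uuuuu)` for any
collection, by construction. The skeleton level keeps only the parent
fragment (counterions dropped), neutralizes charges by hydrogen arithmetic,
clears isotope labels, folds tautomers and strips stereo: it answers "same
basic connectivity?". A provider slot attaches externally computed keys
(e.g. Standard InChIKey) alongside, without re-implementing them.

On the keys, the package computes unique-structure counts with percentages
of the original record count, pairwise overlap matrices, exact 2–4-way Venn
partitions, and release diffs that report, per level, how many unique
structures were maintained, removed and added — plus *skeleton links*: pairs
of releases' records that can only be joined by disregarding a curated
improvement (stereo added, tautomer re-drawn). Stereochemistry-quality
summaries (no/full/partially specified centers, atoms and double bonds) and
molecular-weight profiles (mean, SD, quartiles, histograms with
exclusive-content overlays and mode detection) complete the chemistry side.
The protein side compares accession lists: deduplication against the UniProt
accession grammar, species splits with Swiss-Prot:TrEMBL ratios, n-way
consensus sets and GO top-level molecular-function distributions.

A synthetic-data generator produces paired "releases" as real SD files with
fully known ground truth — planted duplicates, salt/charge/isotope/
tautomer/stereo variants, and curation events between releases — so every
statistic above is testable exactly.

## Worked example

```r
library(chemcollate)

spec <- library_spec(
  6, list(c("salt", "tautomer", "stereo_invert"), character(), character()),
  curation = list(remove = 1, add_stereo = 2, new_records = 1), seed = 1)
g <- generate_library(spec, out_dir = "demo")

old <- key_table(read_sdf("demo/release1.sdf", id_field = "ID")$records)
new <- key_table(read_sdf("demo/release2.sdf", id_field = "ID")$records)

sapply(c("ficts", "ficus", "uuuuu"),
       function(lv) unique_stats(old, lv, 12)$unique_count)
#> ficts ficus uuuuu
#>    12    10     6

release_diff(old, new)
#>   ficts  maintained 9, removed 3, added 3
#>   uuuuu  maintained 5, removed 1, added 1
#>   skeleton-only links: 2
```

Twelve records hold 12 sensitive-level structures but only 10 once tautomer
drawings are folded and 6 skeletons (one per scaffold). Between releases,
one record was deleted and two got stereo added: at the sensitive level the
two curated records look removed-and-re-added, while the skeleton level
recognizes them as the same compounds — the 2 skeleton-only links.

```r
s <- summarize_stereo(read_sdf("demo/release1.sdf", id_field = "ID")$records)
s$counts[1:3]
#> no_atom_stereo full_atom_spec    unspec_atom
#>              2              8              2
```

## Layout

- `R/` — parsing (`read_sdf`/`write_sdf`), normalization and keys
  (`normalize_base`, `compute_keys`, `key_table`), set statistics
  (`overlap_matrix`, `venn`, `release_diff`), stereo audit
  (`summarize_stereo`), MW profiling (`mw_stats`, `mw_histogram`), protein
  comparison (`load_ids`, `species_split`, `consensus`, `go_distribution`),
  synthetic data (`library_spec`, `generate_library`,
  `generate_protein_inputs`), CLI (`chemcollate_cli`, launcher in
  `inst/cli/`).
- `vignettes/chemcollate-methods.Rmd` — the methods notes: model,
  assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
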
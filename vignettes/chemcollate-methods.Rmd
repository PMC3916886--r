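---
title: "Graded chemical identity and collection comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded chemical identity and collection comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemcollate)
```

This vignette records the package's model, its tunable parameters, the
design choices made where several defensible options existed, and the
limits of what the synthetic validation can show about real data.

## Why graded identity

When two compound collections are intersected, the answer depends entirely
on how forgiving the notion of "same compound" is. A database may hold a
drug as its sodium salt, its deuterated analogue, the other tautomer
drawing, or a flat drawing of a chiral structure; between two releases a
record may acquire stereochemistry it previously lacked. A single key
cannot serve all questions, so `chemcollate` computes three, ordered by
normalization aggressiveness:

* **`ficts` (sensitive)** — base normalization only. Distinguishes salt
  forms, charge states, isotope labels, tautomer drawings and
  stereoisomers. Two records share this key only when they are the same
  drawn species up to drawing variance (atom order, resonance form,
  hypervalent conventions).
* **`ficus` (tautomer-invariant)** — additionally folds each fragment to a
  canonical tautomer. Links different tautomeric drawings of one compound
  while still distinguishing everything else.
* **`uuuuu` (skeleton)** — parent fragment only, charges neutralized where
  hydrogen arithmetic permits, isotope labels cleared, tautomer folded,
  stereo stripped. Answers "same basic connectivity and bond orders?".

The class structure is nested: equal sensitive keys imply equal
tautomer-invariant keys imply equal skeleton keys, so unique counts are
monotone non-increasing across the levels for any collection. This nesting
is asserted property-style in the test suite across randomized synthetic
libraries.

Externally computed keys (for example Standard InChIKey from an official
library) can be attached through the provider slot of `compute_keys()`;
they are carried verbatim and never re-implemented.

## Base normalization

`normalize_base()` applies, in fixed order:

1. **Explicit-H folding.** Unlabelled explicit hydrogen atoms become
   implicit counts on their heavy neighbor. Isotope-labelled hydrogens
   (D/T) stay as graph atoms so the label survives at the sensitive levels.
2. **Functional-group transforms.** A deliberately small, closed table:
   pentavalent neutral nitro `R-N(=O)=O` to the charge-separated form,
   hypervalent azide/diazo analogues, and charge-separated sulfoxide
   `[S+]-[O-]` to `S=O`. Each rule strictly reduces hypervalent or
   charge-separated character, so iteration to fixpoint terminates and the
   operator is idempotent. The table is this package's own documented rule
   set; it is *not* a reconstruction of any toolkit's proprietary rules —
   it honors the level contracts (what each level must disregard), which is
   what the comparison statistics rely on.
3. **Charged-resonance canonicalization.** A unit charge is moved along
   conjugated `X(-)–B=C` / `X(+)=B–C` paths (swapping the two bond orders)
   whenever both end atoms keep exact valence; the closure is enumerated
   (capped at 200 forms) and the form with the lexicographically smallest
   canonical serialization is kept. Because the representative is the
   minimum of its orbit and the move set is symmetric, the operator is
   idempotent and both carboxylate drawings, for example, map to one form.

Records whose valence cannot be made exact are flagged `rejected`, excluded
from identity statistics, and tallied — never silently dropped.

## Canonicalization and hashing

Atom ranks come from iterative neighborhood refinement (Weisfeiler–Lehman
colors over element, charge, isotope, H count, and bond-order-labelled
neighborhoods). Remaining ties are broken by individualization: each member
of the first non-singleton class is individualized in turn, refinement is
re-run, and the branch with the lexicographically smallest serialization
wins. This is a standard canonical-labelling scheme; it is exponential in
the worst case but molecules at database scale refine almost completely,
and the test scaffolds (≤ 25 atoms) branch only on genuine symmetries.
Fragments are canonicalized independently and their serial strings sorted,
giving invariance under both atom and fragment permutation.

Stereo enters the serialization as descriptors, not coordinates: a
tetrahedral parity (sign of the signed volume of the substituents ordered
by canonical rank, with the wedge neighbor lifted out of plane) and an
`E`/`Z` label for stereogenic double bonds (side-of-axis test for the
lowest-ranked substituent at each end). Both are derived from the drawing
but expressed relative to canonical ranks, so they survive atom
renumbering. Keys are a 128-bit digest of the serialization rendered as 27
base-32 characters; collisions are treated as impossible at library scale.

## Canonical tautomer

Tautomers are enumerated by 1,3 hydrogen shifts across
`O/N/S(H)–C=C / C=N / C=O` systems (keto–enol, amide–iminol and aza
analogues), breadth-first to a hard cap of 1000 distinct forms, and the
form with the smallest canonical serialization is the representative. The
move set is symmetric (each shift is enumerated in both directions), so a
tautomer orbit is a connected component and any member maps to the same
representative. If the cap is hit, the input form is kept and flagged
`tautomer_cap`; the key is still deterministic.

One rule interacts with stereo: a shift is blocked when it would
rehybridize a *specified* tetrahedral stereocenter or destroy a *specified*
double-bond geometry. Without this, enolization through a specified
α-carbon (as in amino acids) would erase the center and merge enantiomers
at the tautomer-invariant level, violating that level's contract of keeping
stereochemistry. Flat drawings are not protected — their centers carry no
curated information. Consequently, at the skeleton level stereo is stripped
*before* tautomer folding, so the skeleton orbit is never constrained by
stereo protection. A corner case follows from the blocking rule: an enol
drawn with explicit alkene geometry is treated as a distinct, stereo-bearing
species rather than folded into its keto form; we consider this defensible
(the geometry is information) and document it as a known limitation.

## Stereo audit

A potential tetrahedral center is an atom with four graph-distinct
substituents, distinctness judged by the same refinement-derived symmetry
classes used for canonicalization (no CIP machinery); an implicit hydrogen
counts as one substituent. A stereogenic double bond is a non-ring double
bond whose ends each bear two distinct substituents; ring double bonds are
excluded regardless of ring size — the simplest defensible rule. "Specified"
means a parity or geometry is actually derivable from the record (wedge
with its narrow end at the center; non-degenerate 2D coordinates; no
"either" flag). Records without coordinates count all their stereogenic
double bonds as unspecified. Each record falls in exactly one of three
classes per kind (no centers / all specified / at least one unspecified),
so the six summary columns partition the collection twice over — reported
percentages use a caller-supplied *original* record count, so parse
failures and rejections show up in the denominator the way databases report
their raw counts.

## Molecular weight

MW is the sum of standard abundance-averaged atomic weights, with
isotope-labelled atoms contributing their nuclide mass (a small table of
common nuclides; unlisted labels fall back to the mass number). The default
profile weighs the parent fragment of the base-normalized record — salt-free
profiles compare better across databases with different salt-capture
policies — with `parent_only = FALSE` to include counterions. Quartiles use
inclusive linear interpolation (`stats::quantile` type 7) and the SD is the
population form; both choices are stated because published tables rarely
say which convention they used, and we do not claim ours matches any
particular one. Histogram mode detection (strict local maxima above a
minimum mass fraction) is intentionally simple; it is meant to confirm
*planted* bi-/tri-modality in synthetic mixtures, not to be a general mode
estimator.

## Protein sets

Accession lists are validated against the UniProt accession grammar,
de-duplicated, and joined to a required annotation table (species, review
status, semicolon-joined GO top-level molecular-function labels).
Annotations are inputs by design — nothing is fetched live — which keeps
analyses reproducible and desk-scale. Missing annotations degrade loudly:
species `unknown`, review status counted as unreviewed. The
target-species-unreviewed count is surfaced explicitly because reviewed
coverage of well-studied proteomes is essentially complete, making
unreviewed target mappings a useful curation-lapse signal. GO distributions
count each protein once per assigned category (top-level GO terms fork), and
fractions are over assignments, with unannotated proteins reported
separately. Orthologue substitution practices differ between databases;
that is a property of the input lists and is out of computational scope
here.

## Synthetic data: what it emulates, and what it does not

`generate_library()` builds releases from a parameterized scaffold pool
centred on one master graph: a methyl ketone (tautomer site whose enol end
carries two hydrogens, hence never stereogenic), a fluorinated stereocenter
with *no* hydrogen (so no 1,3 shift can ever touch it — its capability is
provable, not probabilistic), a carboxylic acid (charge site), and a
decorable alkyl arm (chain extension × terminal ring size) that makes every
pool member a distinct skeleton; capability-free scaffolds are plain
alkanes. Variants (exact duplicate, salt, charge state, isotope label,
tautomer redrawing, stereo inversion/stripping) and curation events
(remove, add stereo to a flat drawing, redraw tautomer, new record) are
applied by hand-coded record transforms, and all ground truth — unique
counts per level, diff triples, skeleton links, stereo classes, Venn
cells — comes from plan bookkeeping, never from running the pipeline. Atom
orders are randomly permuted (seeded) so recovery also exercises
canonicalization. Output is byte-deterministic for a fixed spec and seed.

Curation events target single-record scaffolds so that expected diffs are
record-exact; weight regimes are log-normal mixtures with closed-form
moments (`sample_mw_mixture()`), chosen because they reproduce the observed
phenomenology of compound collections — unimodal lead-like profiles,
bimodality, and tri-modal patterns when a metabolite resource takes up
large lipid classes — while remaining analytically checkable.

What passing these tests shows: the pipeline recovers planted redundancy
and curation structure exactly, and its identity classes match a
graph-isomorphism oracle on small molecules. What it does not show: rule
coverage on the long tail of real drawing pathologies (exotic hypervalent
conventions, polymer/multi-center records, 3D-only files), agreement with
any historical identifier's numeric values, or tautomer handling beyond
1,3 shifts (1,5 shifts and ring-chain tautomerism are out of scope).

## Problem sizes and numerical choices

The shipped suites use libraries of 2–8 scaffolds (roughly 5–30 records per
release), 50 randomized libraries for the hierarchy property, n = 1000–4500
for distribution recovery, and planted protein universes of a few hundred
accessions — sizes at which every statistic is exact or has closed-form
error bars, chosen to make the full validation run comfortably on a
laptop. Tolerances: distribution recovery asserts within three standard
errors of closed-form values; everything discrete is exact. Ties anywhere
(parent selection among equal fragments, tautomer and resonance
representatives, canonical branching) resolve by lexicographic order of
canonical serializations, so no outcome depends on input order or platform.

## Known limitations

* V2000 only; V3000 blocks are counted parse failures by design.
* No CIP descriptors: substituent distinctness is graph-symmetry based, so
  meso compounds and para-substituted pseudo-asymmetry are judged by graph
  classes, not chemical convention.
* The functional-group table is minimal; real curation pipelines apply
  hundreds of rules. The package's claims are about level *contracts*, not
  numeric agreement with historical identifiers.
* Two records drawn with equal sensitive keys but different wedge
  placements could in principle diverge at the tautomer-invariant level if
  a shift removes one drawing's only wedge; the generator never produces
  such drawings and they have not been observed, but the possibility is
  noted.
* Aromatic-bond kekulization accepts any consistent single/double
  assignment with lone-pair atoms (N/O/S) allowed unmatched; records that
  admit several kekulizations are canonicalized downstream, but pathological
  aromatic systems may fail to kekulize and are then counted as parse
  failures.
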
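Package: chemcollate
Title: Multi-Resolution Chemical Identity and Compound-Collection Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the chemical-structure and protein-target
    content of compound databases across releases and across sources. Reads
    MDL V2000 SD files into a molecular-graph model, applies a graded,
    documented structure-normalization cascade (functional-group and charged
    resonance standardization, salt stripping, charge neutralization, isotope
    clearing, canonical tautomer selection, stereo stripping) and emits
    canonical identity keys at three sensitivity levels, in the spirit of the
    NCI/CADD FICTS, FICuS and uuuuu identifiers. On top of the keys it
    computes unique-structure counts, pairwise overlap matrices, n-way Venn
    partitions, release diffs with skeleton-level linking of curated records,
    stereochemistry-quality summaries and molecular-weight profiles, and a
    parallel toolkit for UniProt accession-set comparison (species splits,
    Swiss-Prot/TrEMBL ratios, consensus sets, GO top-level molecular-function
    distributions). A synthetic-data generator produces database releases and
    protein lists with fully known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
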
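Package: phyloscan
Title: Windowed Phylogenomic Scans for Introgression and Inversion Genealogies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for window-based phylogenomic analysis of multi-species
    whole-genome alignments, modelled on the scans used to place new taxa
    within the Anopheles gambiae species complex. The package reads MAF
    alignments, partitions them into fixed non-overlapping windows on
    reference coordinates, infers a neighbor-joining tree with bootstrap
    support per window, canonicalizes and tallies topologies, classifies
    the placement of a focal taxon to detect introgression tracts and
    chromosomal inversion blocks, and converts patristic-distance
    distributions into divergence-time estimates with bootstrap confidence
    intervals. A multispecies-coalescent simulator with configurable
    introgression pulses and inversion genealogies provides ground truth
    for every stage, and a scaffold-grafting module places de novo
    assembly scaffolds into an existing alignment as a new taxon row.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
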
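Package: scaffeval
Title: Evaluation of Genome Scaffolding Accuracy Against a Reference
Version: 0.1.0
Authors@R: person("Scaffeval", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to measure how well a set of genome scaffolds reproduces
    the layout of a known reference genome. Contig placements are inferred
    from MUMmer show-coords or PAF alignments (or read directly from AGP),
    both genomes are reduced to signed, oriented contig orders, and five
    accuracy metrics are computed: the double-cut-and-join (DCJ) edit
    distance, overall accuracy, grouping accuracy (length-weighted Jaccard
    with optimal one-to-one scaffold/chromosome matching), ordering accuracy
    and orientation accuracy, together with N50 and a no-scaffolding
    baseline. Also included are the experiment generators needed to test a
    scaffolder end to end without external data: equal-size fragmentation of
    a reference into split assemblies, seeded rearrangement perturbation of
    a truth layout, Hi-C read-pair downsampling to a target density, and a
    synthetic genome simulator with repeats and haplotig-like duplicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
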
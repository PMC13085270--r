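# scaffeval

Evaluation of genome scaffolding accuracy against a known reference.

## The problem

Hi-C scaffolders take a fragmented genome assembly (contigs) and propose how
those contigs group into chromosomes, in what order, and in which
orientation. When a finished reference genome exists — or when the contigs
were manufactured by cutting a reference into pieces — the proposed
scaffolds can be scored objectively. `scaffeval` provides that scoring, plus
the generators needed to run the whole experiment without any external data:
split-reference assemblies, Hi-C read-pair downsampling, and seeded
rearrangement perturbations of a truth layout.

The intended users are developers of scaffolding tools and genome-assembly
groups deciding which scaffolder (and how much Hi-C coverage) to use.

## The model

Both the reference and the scaffolds are reduced to *genome layouts*:
ordered, oriented contig sequences — signed permutations of a shared contig
set. Every junction between consecutive contigs is an *adjacency* of two
contig extremities (tail `t` = 5' end, head `h` = 3' end of the forward
strand); chromosome ends are *telomeres*. On this representation the package
computes five metrics:

- **Edit distance** — the minimum number of double-cut-and-join (DCJ)
  operations transforming the scaffolds into the reference, by the closed
  form `d = N − (C + I/2)` where `N` is the number of shared contigs and
  `C`, `I` are the cycles and odd-length paths of the adjacency graph of the
  two layouts.
- **Overall accuracy** — the length fraction of contigs whose *both*
  extremities have the same pairing (same neighbour extremity, or telomere)
  in scaffolds and reference.
- **Grouping accuracy** — scaffolds are matched one-to-one to chromosomes by
  maximum-weight bipartite matching under the length-weighted Jaccard index
  `J = len(shared contigs) / len(contigs in either)`; the score is the
  chromosome-length-weighted mean of matched `J`. One-to-one matching means
  a single mega-scaffold spanning all chromosomes scores poorly rather than
  being credited against each chromosome.
- **Ordering accuracy** — the length-weighted fraction of adjacent contig
  pairs in the scaffolds that are also adjacent (either order) in the
  reference; pair weight is the mean of the two contig lengths.
- **Orientation accuracy** — as ordering, but the junction must pair the
  same extremities (correct relative orientation). Always ≤ ordering
  accuracy.

Also reported: N50 and a *no-scaffolding baseline* (every contig its own
singleton), the score a scaffolder must beat to have added information.

Layouts come from AGP v2.1 files, from exact contig matching inside scaffold
FASTA, or from MUMmer 4 `show-coords` / PAF alignments of contigs to the
reference (best-chromosome placement with an aligned-fraction threshold and
chimera flagging).

## Worked example

Simulate a two-chromosome genome, cut it into 10 kb pieces (the truth
layout), damage the truth with three random rearrangement operations, and
score the result:

```r
library(scaffeval)

syn <- make_synthetic_genome(n_chromosomes = 2, length_range = c(40e3, 60e3),
                             seed = 7)
sp  <- split_reference(syn$genome, piece_size = 10e3)
sp$truth
#> genome_layout: 2 group(s), 11 contig(s), 107,733 bp
#>   chr1 [6]: chr1_p1+ chr1_p2+ chr1_p3+ chr1_p4+ chr1_p5+ chr1_p6+
#>   chr2 [5]: chr2_p1+ chr2_p2+ chr2_p3+ chr2_p4+ chr2_p5+

tr <- random_trace(sp$truth, k = 3, seed = 11)
tr
#> perturbation_trace: k = 3 (seed 11)
#> kinds
#>       fission translocation
#>             1             2

scaffolds <- apply_operations(sp$truth, tr)
score(scaffolds, sp$truth)
#> metrics_report
#>   edit_distance        3
#>   overall_accuracy     0.3713
#>   grouping_accuracy    0.4819
#>   ordering_accuracy    0.6340
#>   orientation_accuracy 0.6340
#>   n50                  10000
#>   contigs evaluated    11 (excluded 0)
```

Three operations put the scaffolds at DCJ distance exactly 3 from the truth
(it can be less when operations cancel). Only 37% of sequence sits with both
neighbours intact; 63% of junction weight is still correctly ordered, and
none of the surviving junctions has a flipped relative orientation
(orientation = ordering here). The baseline shows how much worse *not*
scaffolding would be, in edit distance if not in accuracy:

```r
base <- baseline_report(contig_lengths(sp$truth), sp$truth)
base$edit_distance
#> [1] 9
base$overall_accuracy
#> [1] 0
```

## Command line

The installed script wraps the same operations:

```sh
SCAFFEVAL=$(Rscript -e 'cat(system.file("exec", "scaffeval", package = "scaffeval"))')
Rscript $SCAFFEVAL synth --n-chrom 2 --length 50000 --seed 7 --out syn
Rscript $SCAFFEVAL splitref --genome syn.genome.fasta --preset 10kb --out sr
Rscript $SCAFFEVAL perturb --agp sr.truth.agp --k 3 --seed 11 \
    --contigs sr.pieces.fasta --out pert
Rscript $SCAFFEVAL score --truth-agp sr.truth.agp --agp pert.agp --out report
Rscript $SCAFFEVAL downsample --pairs pairs.tsv --assembly-length 107733 \
    --density 100 --seed 1 --out ds
```

`score` writes a TSV and a JSON report (scaffolds row plus baseline row) and
a `.meta.json` block recording inputs, thresholds and seeds. `compare` ranks
several such reports by mean overall accuracy across conditions
(complete-case by default, `--absent-as-zero` to count failed runs as 0).

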
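---
title: "Measuring scaffolding accuracy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring scaffolding accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffeval)
```

## The evaluation model

A scaffolder's output and the reference genome are both reduced to the same
abstraction: a **genome layout**, i.e. a set of named groups (scaffolds or
chromosomes), each an ordered run of contigs with a `+`/`-` orientation and
a length. Nucleotide sequence plays no role in the metrics; contigs are
atomic markers. All groups are treated as **linear**. This is an assumption,
not a theorem: the evaluated genomes are eukaryotic nuclear genomes, and
linear chromosomes are the only case the generators produce. Circular
chromosomes (organelles, bacteria) are out of scope.

Each layout is decomposed into DCJ **adjacencies** and **telomeres** over
contig extremities. The extremity convention is fixed package-wide: `t` is
the 5' end and `h` the 3' end of the forward strand, so a forward contig is
read `t..h` and a reversed one `h..t`. Reversing a whole group therefore
leaves the adjacency set unchanged — several tests rely on exactly this
symmetry.

## The five metrics

**Edit distance.** The DCJ distance `N − (C + I/2)` over the shared contig
set, where `C` and `I` are the cycles and odd-length paths of the adjacency
graph of the two layouts. The closed form is verified in the test suite
against a breadth-first-search oracle that enumerates actual DCJ moves,
exhaustively for up to three contigs and on 500 random comparisons at four
and five. The BFS searches the full matching space, including states with
circular intermediates, which is what the DCJ model permits; the formula is
exact for that model.

**Overall accuracy** is not printed as a formula in the source material, so
the definition here is the package's own and is stated prominently: a contig
is *correctly placed* when **both** of its extremities have the same pairing
in both layouts (the same neighbour extremity, or a telomere in both), and
the score is the length fraction of correctly placed contigs. This is the
natural per-marker projection of the DCJ adjacency model: a contig scores
only if its entire local neighbourhood is right.

**Grouping accuracy** uses the length-weighted Jaccard index between a
scaffold and a chromosome, combined by **optimal one-to-one matching**
(Hungarian algorithm) rather than greedy best-match. The distinction
matters precisely in the over-scaffolding failure mode: a single
mega-scaffold containing two equal chromosomes has `J = 0.5` against each,
but may be credited against only one, giving 0.25 overall rather than 0.5.
The score is weighted per chromosome (each chromosome contributes its
contig length times the `J` of its matched scaffold, unmatched chromosomes
contribute zero). Weighting per chromosome rather than per scaffold is a
package choice; it penalises both unscaffolded chromosomes and mega-scaffolds
symmetrically.

**Ordering accuracy** scores each adjacent pair in the *assembly* against
adjacency (in either order) in the reference, weighting each pair by the
arithmetic mean of the two contig lengths. "Length-weighted" admits several
readings (mean, min, sum); the mean is used because it makes a junction
between two large contigs worth proportionally more without letting one long
contig dominate both of its junctions entirely.

**Orientation accuracy** tightens ordering: the junction must pair the same
extremities as the reference, which is equivalent to "adjacent and correctly
relatively oriented". Because every orientation-correct pair is
ordering-correct, orientation ≤ ordering holds structurally, and the test
suite asserts it on a thousand random comparisons.

An assembly with no adjacent pairs at all (every contig a singleton — the
baseline) has an empty denominator for ordering/orientation; the package
defines the score as 0 with a warning rather than an error, so that baseline
rows can be tabulated alongside real runs.

## Inferring the truth layout from alignments

The alignment path (show-coords or PAF in, placements out) must resolve
questions the source material leaves open; these rules are artifact-defined:

- Candidate chromosomes are scored by **aligned bases after interval union**
  on the contig's own coordinates, so tandem split hits are not double
  counted; the best chromosome wins.
- Position is the aligned-length-weighted midpoint of the winner's reference
  spans; orientation is the strand carrying the majority of aligned bases.
- A contig is **unplaced** below `min_aligned_fraction = 0.5` of its length:
  half-or-better is the weakest rule that prevents a haplotig-sized spurious
  hit from claiming a placement.
- A contig is flagged **chimeric** when the runner-up chromosome holds at
  least 30% of its total aligned bases — such contigs stay placed (on the
  winner) but the flag travels into reports, since misassembled contigs make
  the "truth" itself suspect.

Internal coordinates are 0-based half-open everywhere; show-coords
(1-based inclusive) and AGP (1-based inclusive) are converted at the I/O
boundary, PAF passes through natively.

## Generators: what the synthetic world does and does not emulate

`make_synthetic_genome` produces uniform-random chromosomes at a target GC
(default 0.4, typical of eukaryotic genomes), optionally implanting copies
from a three-unit repeat library (multi-mapping ambiguity) and
haplotig-like records: 2%-diverged copies of random sub-intervals, matching
the allelic-duplicate divergence that confounds real scaffolding runs. It
does **not** emulate sequencing error, assembly chimeras, centromeric
satellite structure, or realistic repeat families — so a green test
establishes that the *evaluation machinery* is correct, not that any
scaffolder performs well on real genomes.

`split_reference` cuts each chromosome into consecutive pieces of exactly
`piece_size` (presets 10 kb–1 Mb). The trailing remainder is kept when at
least `min_piece` (default half a piece) and otherwise merged into the
previous piece: pieces stay "equal sized" up to one tail per chromosome, and
no sub-half-size fragments are emitted. Pieces are all-forward; orientation
challenges come from the perturbation module, not the splitter.

`downsample_pairs` keeps exactly `floor(density × length/1000)` read pairs,
uniformly without replacement, order-stable and seed-reproducible. The
counting unit is the **pair** (one contact): read bases do not contribute to
contact counts. A `unit = "reads"` mode (two reads per pair) is exposed
because the two conventions differ by a factor of two and published
densities do not always say which was meant. Sampling is not stratified by
contig; no stratification is specified anywhere, and uniform is the only
assumption-free choice.

## The perturbation model

`random_trace` draws `k` operations, each a **single DCJ operation**:

- *inversion* of a contiguous block (reverses order, flips orientations);
- *orientation flip* of one contig (an inversion of block length 1);
- *fission* of a group at an internal boundary;
- *fusion* of two groups (optionally inverting the second);
- *reciprocal translocation*: one cut in each of two groups, crosswise
  rejoin (straight or crossed).

The design constraint was the invariant `dcj_distance(truth, perturbed) ≤ k`
for every seed, which the test suite checks on over a thousand cases. That
constraint rules out the tempting "move a block somewhere else" operation:
excision plus reinsertion is **two** DCJ operations, and an early version
using block moves violated the bound empirically. Consequently ordering
errors are induced by inversions and translocations rather than by block
moves; grouping errors by fission/fusion/translocation; orientation errors
by inversions and flips. Block lengths are geometric with mean 2 contigs —
small enough that single operations stay local, as real scaffolder errors
mostly are.

Operation kinds impossible for the current layout (fusion or translocation
with one group, fission of all-singletons) get weight zero for that step
with a warning, rather than erroring, so dose–response sweeps over `k` run
unattended.

`make_megascaffold` is the deterministic worst case for grouping: all groups
concatenated into one.

## Scoring modes and bookkeeping

The metrics need a common contig set, so contigs present in only one layout
are always excluded, with counts and ids recorded in the report. The
`exclude_unscaffolded` mode additionally drops contigs the assembly left as
singleton groups (configurable via `drop_singletons`): this is the mode that
discounts haplotig-like contigs that scaffolders deliberately ignore, and on
fixtures where the dropped contigs are genuine misfits it never lowers
accuracy (a property in the test suite). When every shared contig is a
singleton, the exclusion is skipped rather than emptying the comparison.

`compare_reports` aggregates runs as complete-case by default (a condition
enters the ranking only when every method has a row), with
`absent_as_zero = TRUE` to count failed runs as zero accuracy instead. Both
are exposed because failed scaffolder runs are common and either convention
is defensible; the default avoids rewarding a method for failing on its hard
conditions.

## Numerical and degenerate-input choices

- Position ties in truth building break by contig id; chromosome groups are
  ordered lexicographically — all outputs are deterministic.
- AGP orientations `?`, `0`, `na` map to `+` with a warning (metrics need a
  concrete orientation).
- `n50` of pieces equals the piece size whenever every chromosome is at
  least two pieces long; the remainder rule guarantees it.
- The Hungarian matching runs on the dense Jaccard matrix; layouts here have
  at most hundreds of groups, where the O(n³) algorithm is instantaneous.
- Seeds: every stochastic entry point takes an explicit integer seed and is
  byte-reproducible under it.

## Known limitations

Only linear chromosomes; no nucleotide-level comparison (a scaffolder that
polishes sequence must be evaluated through the alignment path); no
misassembly detection or contig breaking; exact-substring scaffold-FASTA
parsing fails (by design, with an ambiguity error) when an assembly contains
identical contigs; alternative rearrangement distances (inversion-only,
HP) are not implemented.
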
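---
title: "Haplotype-aware diploid assembly by graph untangling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware diploid assembly by graph untangling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most short-read assemblers treat a diploid genome as if it were haploid:
wherever the two homologous chromosomes differ, the assembly graph forms a
bubble, and the assembler removes one side to produce a single consensus
sequence. For organisms with low heterozygosity that is a reasonable
approximation. For highly heterozygous genomes — many wild invertebrates,
plants, and any genome containing highly divergent regions (HDRs, where the
haplotypes differ by more than ~5% and may carry inversions) — it
discards exactly the biology of interest and often fragments the assembly.

`haplotangle` takes the opposite approach: it never removes bubbles.
Both haplotypes are assembled independently and associated end-to-end as
*bubble pairs* (a primary and a secondary member, distinguished only by
non-N base count), with remaining sequence emitted as non-bubble blocks.
A consensus (pseudo-haploid) sequence can still be produced afterwards
from the primary bubbles plus non-bubble sequences.

## The model and its assumptions

The method rests on two assumptions about diploid genomes:

1. HDRs and low-heterozygosity regions are interleaved in a patchwork, so
   even a highly divergent region is flanked by sequence similar enough to
   form simple bubbles in a de Bruijn graph.
2. Chromosome-scale synteny is conserved between the homologous pair even
   when local divergence is high, so homologous scaffolds can be
   associated by the bubbles they contain.

### Contig assembly

Canonical k-mers (the lexicographic minimum of a window and its reverse
complement) are counted at `k0 = 32`. The initial coverage cutoff is half
the leftmost local minimum of the unsmoothed occurrence histogram — half,
because heterozygous k-mers occur at roughly half the depth of homozygous
ones and must survive the cutoff. The graph is then rebuilt at increasing
k (`k_step = 20`, up to `min(read length - 4, k0 + 3*k_step)`), each time
counting k-mers from the reads plus the previous straight-node sequences
so that thinly covered regions stay connected. Two conventional cleaning
steps are deliberately absent: bubble removal (bubbles carry the
heterozygous signal) and read-based contig correction.

### Coverage normalisation

A k-mer at depth d is seen in `L - k + 1` windows of an L-bp read, so
k-mer coverage shrinks as k grows. Node depths are normalised by
`L / (L - k + 1)` (minus the one count contributed by carried-over
contigs at raised k), which makes `c_hetero` — the length-weighted mean
depth of simple-bubble branches, estimated once on the initial graph —
comparable across the k schedule. `c_hetero` scales every coverage
threshold: anchor bubbles must have both branches at or below
`1.75 * c_hetero`, an untangling center at or below `2 * 1.75 *
c_hetero`, and at least one external at or below `1.75 * c_hetero`. The
1.75 default excludes repeat-derived bubbles while tolerating sampling
noise.

### Untangling

A *cross structure* is a collapsed homozygous center whose two ends each
attach two heterozygous externals; resolving it means deciding whether
(e1,e3)/(e2,e4) or (e1,e4)/(e2,e3) lie on the same haplotype. Evidence
comes from three sources: link counts (read pairs, mate pairs, and single
reads spanning nodes), long-read match-site sums, and linked-read barcode
co-occurrence (sum of read counts over barcodes shared by an external
pair; disabled for centers of 200 kbp or more, beyond linked-read
fragment reach). A solution is adopted only if its score is at least four
times the alternative's *and* at least 1 — the literal 4x rule would
untangle a 0-vs-0 tie, and zero evidence must never phase. Disagreeing
evidence classes veto each other. Resolved centers are duplicated (each
copy inherits half the depth), rewired, and chains merged; the procedure
iterates up to five rounds or until nothing untangles. After the first
round the junction k-mer nodes flanking a center have been absorbed into
merged paths, so cross detection accepts both the junction-mediated shape
and the direct two-edges-per-end shape.

Read mapping uses exact, unique fixed-length seeds of 32, 64 and 96 bp at
32-bp offsets, accepting the shortest unique length (shortest-first
maximises sensitivity; a seed occurring more than once anywhere in the
node set never places). Libraries are processed in ascending insert-size
order, and per-library evidence is evaluated before the combined set.

### Scaffolding and its untangling

Links are lifted from contigs to scaffold ends, bundled per oriented
scaffold pair (minimum support 2; the gap is the support-weighted
median). Scaffolds shorter than the smallest library insert are excluded
from the graph — they are mostly collapsed homozygous pieces that belong
to both haplotypes, and gap closing restores their sequence into each
haplotype afterwards — unless they contain anchor bubbles, which marks
them as heterozygous candidates. Cross structures in the bundle graph are
resolved with the same evidence rules. Because long-insert libraries span
several scaffolds, an end legitimately carries bundles to every scaffold
within insert reach; a join is made to the nearest partner by estimated
gap when the choice is mutual and no second partner competes for the
same span (within a 200-bp slack), which is a transitive-reduction-style
rule rather than a naive single-bundle condition.

### Haplotype synteny-based correction

Each scaffold is tiled into anchor segments (unique occurrences of anchor
bubble branches, annotated with the scaffold-ID of the counterpart
branch) and non-anchor segments (ID 0). The majority counterpart `B_max`
maximises the length sum of supporting segments; the forward division
score walks from the first to the last `B_max` segment, unchanged on
non-anchors, down by the segment length on `B_max` anchors and up on
foreign anchors; a positive maximum moves the boundary (ties to the
smaller index; a symmetric backward pass corrects the other end). The
node is reduced to the corrected range, out-of-range pieces become
separate nodes, and a node is additionally divided at an internal anchor
whose counterpart is the edge anchor of another node (both ends of a
bubble pair must correspond). The loop runs until a round performs zero
divisions; counting only actual changes guarantees termination. After
convergence, scaffolds whose majority counterparts are mutual become
bubble pairs; the member with more non-N bases is the primary (ties break
to the smaller scaffold id, for deterministic output).

One consequence of the literal trimming rule is that anchor-free scaffold
termini (typically the few dozen bases beyond the outermost heterozygous
site) are split off at every iteration; at the default simulation scale
this costs about one 1-kbp evaluation fragment per block end.

### Gap closing and consensus

Gap closing assigns reads to each N run by unique placements in the
flanks (or a uniquely placed mate), then: (i) if the flanks overlap
exactly by 30 bp or more, the gap is a rendered negative-gap join and is
closed by the overlap; (ii) otherwise a local de Bruijn graph (k = half
the final graph k) is built from the assigned reads and the gap is
replaced only if exactly one simple path connects the two flank anchor
k-mers within ten times the gap estimate. Non-N bases are never touched.
Consensus scaffolds concatenate primary bubbles and non-bubble sequences
over unambiguous exact (k-1)-mer end overlaps, then pass through the
link-based scaffolder; secondary bubbles are excluded by construction.

The outer loop — untangle, scaffold, correct, pair, close gaps — runs
twice by default; the second iteration re-enters scaffolding with the
previous blocks as nodes, which heals divisions introduced by the
correction step.

## The simulator, and what passing tests do not show

`simulate_diploid()` draws haplotype A as i.i.d. uniform bases
(optionally with planted exact repeats) and derives haplotype B by
Bernoulli per-base SNVs (default 1%), geometric indels (mean 3 bp at
5e-4/bp), and per-HDR divergence with optional inversion. Every variant
is recorded; `reconstruct_hap_b()` round-trips exactly.
`simulate_reads()` draws fragments alternately from the two haplotypes:
inward paired-end, outward mate-pair, barcoded linked-read pairs
(`BX:Z:` tags, one barcode per DNA fragment), and long reads with i.i.d.
substitution errors. Everything is deterministic under the stated seeds.

The standard conditions used by the test suite and `scripts/acceptance.R`
are a 200-kbp diploid at 1% background heterozygosity with one 10-kbp
inverted HDR at 5% divergence, sequenced error-free at 40x PE (insert
400, 150-bp reads) and 40x MP (insert 3000). These sizes keep a full
two-arm run within a couple of minutes on one core while leaving every
graph phenomenon of interest present (several hundred cross structures,
an inversion, collapsed homozygous runs longer than the PE insert).

A uniform random background is *easier* than real genomes: no
interspersed repeat families, no GC bias, no sequencing error, perfectly
known inserts. Passing the simulation-based tests therefore demonstrates
the correctness of the graph algorithms and the evidence rules, not
performance on real libraries; in particular the error-free setting means
the k-mer histogram has no noise peak and the initial cutoff falls back
to 1, and repeat-induced mis-joins are exercised only through the planted
repeat option.

## Evaluation metrics

* `assembly_stats()`: NG50 is the largest length whose
  longest-sequences-first cumulative sum strictly exceeds half the genome
  size, LG50 the number of such sequences; blocks under 500 bp are
  excluded, and contig statistics split at every N run.
* `fragment_recall_precision()`: both sets are cut into non-overlapping
  1-kbp (or 5-kbp) fragments from position 0 (trailing partials and
  N-containing fragments dropped); matching is exact and
  strand-symmetric.
* `build_het_pairs()`: the phasing currency — ~1-kbp homologous sequence
  pairs with at least one difference, built by all-vs-all alignment
  (minimap2), discarding near-exact hits (edit distance bounded by the N
  content of the aligned regions), keeping the best hit per contig at
  identity >= 0.8 and length >= 500, cutting blocks where the shorter
  side holds 1000 bases, and confirming each side by exact matches in
  the source set. The confirmation threshold defaults to 2 (appropriate
  for redundant synthetic long-read sets); `truth_het_pairs()` tiles a
  known haplotype pair into 10-kbp pseudo-contigs and uses a threshold
  of 1, since each locus then occurs exactly once.
* `phased_pair_rate()`: a pair is phased when both sides match the block
  set exactly, and bubble-phased when the two sides land in the two
  members of one bubble pair; rates are windowed on source coordinates.
* `count_switch_errors()`: block fragments are assigned their haplotype
  of origin by exact match; fragments matching both haplotypes are
  phase-uninformative and fragments matching neither are excluded from
  adjacency. Adjacent informative fragments flipping haplotype at
  collinear coordinates count one switch error; adjacent assigned
  fragments violating order, orientation or distance (beyond one
  fragment length of slack) count one mis-assembly. This classifier is
  this package's formalisation; fragment length and slack are
  parameters.
* `find_reference_absent_bubbles()`: 1-kbp bubble fragments whose best
  reference alignment is missing, shorter than 500 bp or below 0.9
  identity are reference-unaligned; unaligned fragments are kept only
  with an exact match in a trusted set (excluding mis-assemblies), and a
  bubble is reported when primary + secondary length >= 100 kbp and the
  confirmed unaligned rate >= 0.25.

## Numerical and degenerate-input choices

* Histogram smoothing window is 1, i.e. no smoothing; the local-minimum
  scan starts at occurrence 2 and ties resolve to the smallest
  occurrence; a monotone histogram yields cutoff 1 with a warning.
* k-mers containing N are never counted, so N runs in gapped nodes act
  as hard breaks.
* Self-reverse-complement (palindromic) k-mers are treated as junctions.
* An empty graph after the cutoff, a bubble-free graph (c_hetero
  undefined, synteny correction disabled), and barcode-free linked reads
  all degrade with warnings rather than errors.
* All deterministic tie-breaks are documented at the point of use:
  smaller scaffold-ID in the majority argmax, smaller index in the
  division-score argmax, smaller id for equal non-N counts in bubble
  pairing.
* Scaffold join gaps are rendered as `max(estimated gap, 1)` Ns so joins
  stay visible in FASTA; true negative gaps are recovered at gap-closing
  time through the exact flank overlap.

## Worked example

```{r example}
library(haplotangle)

spec <- diploid_spec(length = 200000, snv_rate = 0.01,
                     hdr = data.frame(start = 95001, length = 10000,
                                      divergence = 0.05, inversion = TRUE),
                     seed = 1)
dip <- simulate_diploid(spec)
libs <- list(
  simulate_reads(dip, library_spec("paired", insert_mean = 400,
                                   coverage = 40, seed = 101)),
  simulate_reads(dip, library_spec("mate", insert_mean = 3000,
                                   coverage = 40, seed = 102)))
res <- run_pipeline(libs, pipeline_config(genome_size = 200000))
print(res)

rp <- fragment_recall_precision(res$blocks, c(dip$hap_a, dip$hap_b))
hdr <- hdr_inversion_check(res$blocks, dip$hap_a, 95001, 10000)
```

## Known limitations

* Desk scale only: string-keyed hash tables and in-memory data frames are
  sized for hundreds of kilobases to a few megabases, not gigabase
  genomes.
* Diploid only; polyploid untangling would need more than two center
  copies.
* The seed mapper requires exact 32-mers, so short-read error rates
  above ~1% thin the evidence; the contract matches the accurate-reads
  design of the method.
* Long reads contribute evidence (via minimap2 alignments and the
  match-site method) but there is no long-read-only assembly path.
* The switch-error classifier depends on exact fragment matches and
  under-assigns in regions assembled with even a single base error.
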
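---
title: "Multi-sample transcript meta-assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sample transcript meta-assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metassembler)
```

## The problem

A single RNA-seq sample — above all a single cell — rarely sequences
every junction of every expressed transcript, so single-sample
assemblies are fragmented. When many samples of the same tissue or cell
population are available, a junction missed in one sample is usually
covered in another. `metassembler` assembles all samples jointly: it
keeps one splice graph per sample (so samples are never forced into a
consensus), but lets samples *support* one another in three ways —
restoring missed junctions, corroborating edges during graph
decomposition, and informing a learned confidence score.

## Splice graphs

For each gene locus and sample we build a weighted DAG `G = (V, E, w)`.
Junctions (donor, acceptor) extracted from spliced alignments form the
edges; their coordinates partition the covered genome into (partial)
exons, the vertices. A vertex's weight is its average per-base
coverage; a junction edge's weight is the number of reads spanning it.
Adjacent vertices with continuous coverage are linked by *adjacent
edges*. A source `s` is connected to every in-degree-0 vertex `u` with
weight `w(s,u) = sum of u's out-edge weights` (and symmetrically a sink
`t`), after which transcripts are exactly the s–t paths.

All coordinates are 0-based half-open internally; GTF input/output is
the single conversion point to 1-based inclusive.

Graphs from different samples are grouped per locus by single-linkage
clustering on the Jaccard similarity of their splice-position sets,
stopping at a size cap (by default the number of samples) and below a
minimum similarity of 0.1 — two junction-free graphs have an undefined
(0/0) similarity, which we define as 0. Each cluster's *combined graph*
is built from the pooled reads of all members.

## Two-stage bridging

A paired-end fragment sequences its two ends but not its middle.
*Bridging* infers the missing middle as a path between the mates'
vertex chains. Among connecting paths we take the bottleneck-optimal
one — maximize the minimum edge weight, break ties by fewer junctions,
then by smaller exonic length — by dynamic programming in coordinate
order, which is deterministic and linear in the (small) locus graph.

Bridging runs in two stages. Stage 1 bridges every fragment against its
own sample's graph. Only fragments that fail — typically because their
sample never sequenced a junction the fragment straddles — are retried
against the combined graph. Fragments bridged there ("rescued") are
turned into pseudo-reads covering their inferred middle, and the
sample's graph is rebuilt with them: missed junctions reappear with a
weight equal to the rescued fragment count, vertices are split at the
new splice positions, and coverages are corrected. One refinement round
is performed; afterwards all fragments are re-bridged against the
refined graph to produce the final phasing paths. A fragment bridged in
its own sample is never re-bridged against the combined graph — the
combined graph's own phasing set uses a fixed coordinate *translation*
of those paths instead, so no sample ever imports junction combinations
it did not itself express.

## Edge supports

For every edge `e` of every graph in a cluster of N members we compute
a length-N vector `M_e`, the support each member lends to `e`:

* **junction edges** are supported by a junction with identical
  coordinates (support = its weight);
* **adjacent edges** by an identical adjacency, or — failing that — by
  a vertex that strictly spans the boundary, i.e. covers the base on
  each side of it (support = edge weight, or vertex coverage). When
  both match, the edge rule wins. A vertex that merely *starts* at the
  boundary provides no evidence of contiguity and does not count;
* **starting/ending edges** by a boundary edge of the member at the
  located coordinate, optionally reached across one adjacent hop of at
  most 200 bp (`max_boundary_ext`); the threshold is strict (201 bp
  yields 0).

Supports compose by elementwise minimum: a member corroborates a path
only as much as its weakest constituent edge.

## Phase-preserving decomposition

Each graph is decomposed into parallel s–t paths by removing one vertex
at a time. Trivial vertices (in- or out-degree 1) merge all in/out edge
pairs. For a non-trivial vertex we build a bipartite graph over its
in- and out-edges; phasing paths threading the vertex dictate links,
and every in/out edge untouched by phasing is linked to the
opposite-side edge maximizing the summed composed support
`sum_j min(M_in[j], M_out[j])` (left side first, then right, each in
edge order; ties take the first edge). Because every phasing pair
becomes a merged edge and every edge keeps at least one partner, two
guarantees hold structurally: every phasing path appears contiguously
in at least one output transcript, and every junction edge is covered
by at least one transcript.

Weights are reallocated on the in-side: a link `(e_in, e_out)` receives
`w(e_in) * w(e_out) / sum of w over e_in's linked out-edges` (equal
split if that sum is zero). Each vertex removal therefore conserves the
total in-flow, and the summed abundance of the final transcripts equals
the total source outflow exactly (the tests assert a 1e-6 relative
tolerance to allow floating-point accumulation). For a pass-through
vertex (one in, one out) the merged edge keeps the in-edge's weight. A
fuller flow-balancing scheme (LP-based) would be possible but is
deliberately out of scope; proportional allocation is deterministic and
conservation is what the downstream abundance feature relies on.

Decomposition order: all trivial vertices first (cheapest and
risk-free), then the non-trivial vertex with the smallest
in-degree x out-degree, leftmost on ties. Termination is guaranteed —
each step removes one vertex. Phasing paths that a forced merge makes
unrepresentable are dropped and counted; with consistent phasing (paths
that are real walks in the graph) none are dropped.

## Features and scoring

Every candidate transcript is described by 50 features in four groups
(see `feature_schema()` for the exact order and scaling class):

* *abundance* (14): inferred abundance, supporting-sample count and
  total, bottleneck edge weight and its supports, abundance relative to
  the locus flow, path coverage;
* *graph structure* (12): vertex/junction counts of the individual and
  combined graphs, cluster size, exon/intron counts and lengths,
  whether the same chain was assembled from both the individual and the
  combined graph and with what abundance;
* *boundary* (14): start/end edge weights, their cross-sample boundary
  supports, terminal exon lengths and coverages, counts of competing
  start/end edges — start/end prediction is the hardest part of
  assembly from short reads, especially for partially sequenced
  single-cell transcripts;
* *intron* (10): retained-intron indicators — a junction lying wholly
  inside one exon of the candidate — with the "competitiveness" of the
  intronic coverage against the spliced junction's weight, plus
  junction weight/support summaries.

Each feature is declared `scale` (doubles when every read is
duplicated), `invariant`, or `log`; the declaration is tested. Ratio
and count features normalized this way are what lets one model serve
protocols with very different depths.

The scorer is a probability random forest, 100 trees, maximum depth 20
(`ranger`), trained on candidates labeled by exact intron-chain match
against an annotation. Candidates with identical intron chains
(across samples, or from an individual and the combined graph) are
aggregated into a *meta-transcript* whose score is the mean member
score and whose representative exon chain comes from the most abundant
member. The default emission threshold is 0.5; 0.2 is the recommended
hard floor. Models persist with a feature-schema hash and training
digest and refuse to score mismatched features.

## Evaluation

A multi-exon prediction matches if its intron chain equals an annotated
transcript's exactly (same chromosome and strand). Matching is
set-valued: duplicate predicted chains count once, and single-exon
transcripts are excluded from both sides. Precision–recall curves sweep
the score (or abundance, for a baseline ranking); thresholds above the
maximum score — whose prediction set is empty and whose precision is
undefined — are not part of the curve, which also makes the partial AUC
invariant to grid refinement. pAUC integrates the piecewise-linear
curve by trapezoids over a recall (or precision) interval; when two
rankings are compared the interval is the intersection of their spans.

## The simulator

`sim_config()` / `end_to_end_fixture()` generate ground-truthed
multi-sample bundles: random gene scaffolds of 3–12 exons (80–600 bp,
introns 200–5000 bp); isoforms skip 1–2 interior exons of their
scaffold — the typical alternative-splicing event granularity; isoforms
differing in many exons at once would overstate branch ambiguity
relative to real annotation. Every sample expresses an independent
random fraction `sharing` (p) of the transcript set, with log-normal
(meanlog 1, sdlog 1) per-sample expression giving a realistic ~30-fold
dynamic range around a configurable mean depth. Reads are *perfect
spliced alignments* written directly as coordinate-sorted SAM — the
assembler's contract starts at alignments, so no sequence-level error
model is included. Junction dropout removes, in a designated sample,
every read spanning a designated junction, manufacturing exactly the
rescue scenario while keeping fragments whose unsequenced middle
straddles it.

What passing tests on these fixtures do **not** show: robustness to
alignment artifacts (soft-clips at junctions, multimappers), sequencing
error, PCR duplicates, UMI structure, or annotation incompleteness.
The simulator is a test harness for the algorithms, not a benchmark of
biological fidelity.

## Study conditions used by the tests

The test-suite fixtures are sized for a laptop-class run: the scorer is
trained on a 20-locus, 5-sample bundle with half-shared truth sets
(p = 0.5, mean depth 12x) and applied to disjoint transcriptomes
(8 loci, 3 samples, 6x) for the transfer checks, and to a clean
10-locus, 5-sample, 20x bundle with p = 0.9 for end-to-end recovery at
the 0.2 floor. Property suites use 200 random graphs of up to 15
vertices (decomposition) and 100 random 3-sample clusters (supports).
The null control for the scorer permutes labels across the full
synthetic row set before splitting, so the held-out null AUC is a
clean Mann–Whitney statistic.

## Known limitations

* Clip-signal-based junction inference is not implemented; junctions
  come from `N` CIGAR operations only.
* Unstranded reads are assigned to the stranded locus they overlap
  most; truly unstranded loci are assembled on strand ".".
* The bridging objective is bottleneck-optimal DP, not the full
  nomination/voting scheme of dedicated bridging tools.
* Abundances are flow allocations, not EM estimates; they are meant as
  features and rankings, not as quantification.
* Meta-transcript scores are averaged member scores; learning a direct
  meta-level score is future work.
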
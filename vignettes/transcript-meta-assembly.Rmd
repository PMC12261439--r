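---
title: "Cell-specific transcript meta-assembly: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-specific transcript meta-assembly: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txfuse)
```

## The problem

Short-read single-cell RNA-seq rarely covers a transcript end to end in any
one cell: coverage gaps and dropout leave each cell's assembly full of
*transcript fragments* — partial isoforms truncated at arbitrary exons. Yet
the same transcript is often expressed in many cells, each contributing a
different fragment. txfuse merges per-cell assemblies into full-length
isoforms and then decides, per cell, which merged isoforms that cell actually
expresses.

The unit of identity throughout is the **intron chain**: the ordered list of
splice junctions (donor, acceptor pairs) of a multi-exon transcript, keyed by
chromosome and strand. Two transcripts are the same isoform exactly when
their chains are identical; terminal exon boundaries are deliberately
ignored, because fragment ends are incomplete by nature. Single-exon
transcripts carry no junctions and are excluded on input.

## Stage 1: the transcript fragment graph

Every distinct chain observed in any cell becomes one vertex (identical
chains from different cells collapse, keeping all supports). A directed edge
$u \to v$ exists when a suffix of $u$'s chain equals a prefix of $v$'s chain
— sharing $k \ge 1$ junctions — and $v$ extends strictly beyond $u$ on the
right. Chains fully contained in another chain get no edge to their
container; containment is not extension. Because an edge forces the target to
reach strictly further right, the graph is acyclic by construction.

```{r graph-example}
fx <- make_end_to_end_fixture("tiny", seed = 1)
g <- build_graph(fx$assemblies)
c(vertices = length(g$vertices), edges = nrow(g$edges),
  components = length(unique(g$comp)))
```

## Stage 2: path search by merging score

A path through the graph merges its vertices' chains into one candidate
isoform $p$. Its quality is the **merging score**
$F(p) = BJ(p) \cdot NJ(p)$, where $NJ(p)$ is the number of junctions in the
merged chain and $BJ(p)$ is the *bottleneck*: the smallest per-junction
support $J(j, p)$, the sum of scores of all fragments (from all cells) that
contain junction $j$ and are *compatible* with $p$. A fragment is compatible
when it shares at least one exact junction with $p$ and has no junction whose
intron interval overlaps one of $p$'s intron intervals without matching it —
the signature of a conflicting isoform.

$F$ is not monotone along a path: appending a junction raises $NJ$ but can
lower $BJ$, and compatibility of earlier fragments can flip as the chain
grows. The search therefore recomputes $F$ from scratch on every merged
chain and uses a capped dynamic program over a topological order: each vertex
seeds its own single-vertex path, extends the paths kept at its
predecessors, and retains only the top `pn` paths per vertex (default 15) and
`pc` per connected component (default 100), ranked by $F$, then $NJ$, then
chain order. With the caps disabled the search provably returns the full
exhaustive enumeration, which is how it is property-tested.

One subtlety the test suite caught: the same merged chain is often reachable
through several vertex routes (per-cell windows of one transcript at
different granularities). Such duplicates are identical candidates, so
trimming deduplicates chains before applying a cap; otherwise duplicates
crowd genuine isoforms out of the `pc` slots.

```{r search-example}
cands <- search_all(g)
head(data.frame(
  chain = vapply(cands, `[[`, "", "key"),
  F = vapply(cands, `[[`, 0, "F"),
  NJ = vapply(cands, `[[`, 0L, "NJ")), 5)
```

## Stage 3: two-stage random-forest scoring

Candidates are scored by two probability random forests (100 trees, maximum
depth 12, fixed seed, single-threaded for determinism):

* the **general** model sees 30 candidate-level features — five summary
  statistics (min, median, mean, max, population SD) over per-junction
  support scores, supporting-cell counts and supporting-fragment counts,
  plus bottleneck/merging score, cell-support proportions, and
  fragment-connecting structure (vertex count, overlap lengths, longest
  single fragment fraction). Candidates scoring below a threshold
  $\theta$ (default 0.2; a score exactly at $\theta$ is kept) are discarded —
  this is also the mechanism that rebalances classes for the second stage;
* the **specific** model sees all 51 features — the 30 general ones plus 21
  computed per (candidate, cell): the same summaries restricted to that
  cell's fragments, the cell's bottleneck and its rank across cells,
  library size, full-chain flags, and best-fragment statistics. A pair is
  *eligible* when the cell expresses at least one of the candidate's
  junctions; only eligible pairs are scored, which is what makes assignment
  cell-specific.

Training labels come from per-cell ground truth (or a reference annotation
when no per-cell truth exists). Chromosomes 1–9 train; all others are held
out, so every reported number is out of sample. A candidate enters a cell's
final assembly when its probability reaches $\tau$ (default 0.5); the full
scored table is kept regardless, because evaluation sweeps scores.

## Evaluation protocol

A prediction *matches* when its chain equals a truth chain exactly.
Duplicate predictions of one chain earn credit once but all count in the
denominator. Precision is matched-distinct over assembled. To compare two
methods of different sensitivity, **adjusted precision** removes the
lower-scored predictions of the more sensitive method one at a time until its
distinct-match count first equals the other's, then reports the precision of
the retained set — a point on its precision–recall curve. Evaluation runs in
two modes per cell: *cell-specific* (against that cell's own truth) and
*general* (against the union over cells); the gap measures whether
transcripts are assigned to the right cells rather than merely being correct
somewhere.

## The synthetic-data generator

The generator is first-class because the method's claims are about recovery
and per-cell assignment, which require planted truth. It simulates, at desk
scale: genes with shared exon-slot boundaries (so isoforms of a gene share
junctions and create both compatible and conflicting configurations), a
forced anchor junction shared by all isoforms of a gene, per-(isoform, cell)
expression, fragmentation into contiguous windows overlapping by at least
one junction — which guarantees that with zero dropout every expressed chain
is reconstructible as a graph path — dropout, truth-correlated noisy scores,
and decoy fragments with one displaced acceptor that exercise the conflict
predicate. Genes rotate over 18 chromosomes so both sides of the 1–9
train/test split are populated. Scales: `tiny` (3×3), `small` (50×10),
`medium` (300×30) — sizes chosen so the full pipeline runs in minutes on one
CPU while still yielding stable medians over cells.

```{r sim-example}
str(fx$truth_by_cell)
```

## Design decisions and numerical choices

* **Conflict definition.** "Conflicting junction" is implemented as interval
  overlap between intron intervals without exact identity. Stricter
  interleaving rules were considered and rejected: interval overlap is the
  unambiguous, checkable reading.
* **Thresholds.** $\theta$ keeps scores $\ge$ the threshold; $\tau$ defaults
  to 0.5 but the scored table is emitted in full.
* **Determinism.** All ranking ties are broken totally (F desc, NJ desc,
  chain lexicographic); forests are seeded and single-threaded; duplicate
  candidates resolve by an input-order-independent representative. Identical
  inputs give byte-identical outputs.
* **Population SD** in feature summaries, so single-observation blocks give
  0 rather than NA.
* **Score normalisation.** Input transcript scores (e.g. read coverage) are
  min–max normalised per cell only when outside [0, 1].

## Limitations

* Matching is exact intron-chain identity; no fuzzy terminal-exon matching
  and no nucleotide-level metrics.
* The two forests are not calibrated; probabilities are used for ranking and
  thresholding only.
* Cross-validation against an external transcript-comparison tool is not run
  in this package's test suite; the matching convention (duplicates count
  once toward matches) mirrors the standard tool's intron-chain class but is
  verified against hand-derived cases and an independent in-suite oracle
  instead.
* The generator plants junction-level structure only: no read-level
  simulation, no realistic expression magnitudes, no batch effects.
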
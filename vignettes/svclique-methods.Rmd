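---
title: "Calling structural variants from long-read alignments with svclique"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from long-read alignments with svclique}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svclique)
```

## The problem

Structural variants (SVs) — deletions, insertions, duplications and
inversions of 50 bp and more — are poorly captured by short-read callers
because a short read rarely spans a whole event. Long reads (PacBio,
Nanopore) do span most SVs, but their 5–15% error rate, dominated by
small indels, means SV evidence arrives fragmented and jittered across
reads. `svclique` detects SVs from long-read alignments (SAM/BAM with
supplementary records) in three stages: **collect** per-read signatures,
**cluster** them across reads, and **combine** clusters into classified
calls.

## Signatures

A *signature* is evidence from a single read, represented as a typed
genomic interval \((T, C, B, E)\) on the reference. Two evidence classes
exist:

* **Intra-alignment** signatures are large gaps inside a single alignment:
  a CIGAR `D` run of at least `min_sv_size` bp is a deletion signature, an
  `I` run an insertion signature. Because indel sequencing errors shatter
  one event into adjacent runs, same-type gaps separated by at most
  `gap_merge_tolerance` aligned bases are merged before thresholding.
* **Inter-alignment** signatures come from the relative placement and
  orientation of a read's split alignment segments, examined pairwise and
  in consecutive triples along the read: a reference gap exceeding the
  read gap (deletion), a read gap exceeding the reference gap (insertion),
  a backward jump on the reference (tandem duplication), a strand-flipped
  middle segment between co-oriented flanks (inversion), reference-adjacent
  flanks with a middle segment mapping elsewhere (duplication with a
  detected genomic origin), and any remaining junction between distant loci
  (a breakend on each side, each recording the other as its mate).

Six signature types result: `DEL`, `INS`, `DUP` (insertion with known
origin), `INV`, `TAN` and `BRK`. Insertion signatures use the span
convention \(E = B + \text{inserted length}\), so that span comparisons in
clustering compare inserted lengths and same-length insertions cluster
tightly even though they occupy a single reference point.

## Clustering with the span-position distance

Signatures of one SV coming from different reads have similar positions
and spans but often little or no literal interval overlap, so
overlap-based interval distances are uninformative here. The
*span-position distance* (SPD) between two signatures combines a span
difference and a positional difference:

\[
\mathrm{SPD} = \underbrace{\frac{|span_1 - span_2|}{\max(span_1,
span_2)}}_{\mathrm{SD}\,\in\,[0,1)} \;+\;
\underbrace{\frac{\min(|B_1 - B_2|,\, |E_1 - E_2|,\, |mid_1 -
mid_2|)}{N}}_{\mathrm{PD}/N}
\]

The normalization constant \(N\) (default 900 bp) is the exchange rate
between the components: two equal-span signatures 900 bp apart weigh the
same as two co-located signatures of maximally different spans.

Per signature type and chromosome, signatures become vertices of an
undirected graph with an edge wherever \(\mathrm{SPD} < T\) (strictly;
default \(T = 0.7\)). Clusters are the **maximal cliques** of this graph,
enumerated with the Bron–Kerbosch algorithm with pivoting: a clique is a
set of signatures that are *all mutually* compatible, which keeps two
nearby but distinct SVs apart even when a stray signature sits between
them. Because \(\mathrm{PD} \ge N\,T\) alone already implies
\(\mathrm{SPD} \ge T\), pairs beyond that positional bound are pruned
without computing SD; the pruned graph is provably identical to the full
one (asserted by a property test).

Each cluster receives a score \(S \in (0, 100]\) from four components:
the member count \(n \in (0,40]\) with at most 20 signatures counted per
evidence class; a bonus \(b\) of 10 for the presence of intra-alignment
evidence plus 20 for inter-alignment evidence; a positional-consistency
term \(sp = 10\,(1 - \min(1, s_{pos}/\overline{span}))\); and a
span-consistency term \(ss = 20\,(1 - \min(1, s_{span}/\overline{span}))\).
High scores mean many concordant signatures of both classes.

## Combination into five classes

`DEL`, `INV` and `TAN` clusters directly become deletion, inversion and
tandem-duplication calls. `DUP` clusters become interspersed duplications
carrying their origin locus. An `INS` cluster whose insertion point lies
within `match_distance` of an unconsumed `BRK` cluster is upgraded to an
interspersed duplication whose origin is the breakend's mate locus
(greedy 1-to-1 pairing by distance); remaining `INS` clusters are novel
element insertions. An interspersed duplication whose origin overlaps a
deletion call is flagged as a potential cut&paste insertion — the copy
and the move are indistinguishable from reads alone, so the class is kept
and only annotated. Breakend clusters without an insertion partner emit
no call: translocation calling is out of scope.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_sv_size` | 50 | bp | smallest reported event; the conventional SV size floor |
| `min_mapq` | 20 | — | drops ambiguous placements that fake inter-alignment signatures |
| `gap_merge_tolerance` | 10 | bp | merges error-shattered CIGAR gaps |
| `segment_gap_tolerance` | 100 | bp | "reference-adjacent" slack for duplication flanks and read-space contiguity |
| `min_distance` | 10 000 | bp | jumps at least this far are duplication transits or breakends, not deletion/tandem geometry |
| `max_segments` | 10 | — | reads split further are treated as mapping artifacts |
| `normalization_N` | 900 | bp | SPD exchange rate |
| `edge_threshold_T` | 0.7 | — | strict clustering-edge threshold |
| `match_distance` | 100 | bp | INS-to-BRK pairing radius |
| `min_score` | 0 | — | BED output filter; kept at 0 so consumers sweep cutoffs themselves |

`min_sv_size`, `normalization_N` and `edge_threshold_T` follow the
method's published settings. The segment heuristics
(`segment_gap_tolerance`, `min_distance`, `max_segments`) are this
package's own choices, set to separate duplication transits from
alignment jitter; they are exposed as arguments and CLI flags.

## The fixture simulator

`simulate_reference()`, `implant_variants()` and
`synthesize_alignments()` generate truth-labelled inputs so every stage
is testable without an external aligner or reference download. The
simulator emulates exactly the alignment artifacts the caller consumes:
split alignments with correct strands and clips around inversions and
duplication transits, backward reference jumps at tandem-duplication
junctions, CIGAR `D`/`I` runs for events up to 2 kb inside one record and
split representations above that, supplementary-record flags, and (in
noisy mode) indel-dominated sequencing errors injected at a configurable
rate (default 10%, split 6% insertion / 3% deletion / 1% substitution,
the error mix typical of PacBio CLR data). Read lengths are log-normal
with an 8 kb median truncated to 0.5–50 kb; SV sizes are log-uniform on
50 bp–10 kb, mirroring the strong small-event skew of real SV size
distributions; implanted variants are non-overlapping with a 2 kb
minimum spacing. Aligned stretches shorter than the minimum SV size are
treated as unalignable.

The standard benchmark scenario — used by the acceptance suite — is a
500 kb two-chromosome genome with 60 homozygous SVs (20 deletions,
10 inversions, 10 tandem duplications, 15 interspersed duplications,
5 novel insertions) at 6× coverage; this size keeps a full
simulate–call–evaluate round under half a minute while still providing
several spanning reads per event.

What the simulator does **not** model: repeat landscapes and segmental
duplications (the main cause of mapping ambiguity in real genomes),
chimeric library artifacts, base-quality information, reference bias and
aligner-specific breakpoint jitter beyond the injected indel noise.
Passing the synthetic benchmark therefore demonstrates correctness of
the signature/cluster/combine logic under realistic alignment geometry,
not performance on repeat-rich real data.

## Numerical choices and degenerate inputs

* The "genomic position" entering \(s_{pos}\) is the interval midpoint,
  matching the midpoint term of PD; the standard deviations are
  *population* standard deviations so singleton clusters are well-defined
  (0) without special cases.
* Cluster consensus coordinates are the medians of member begins and
  ends (rounded); for duplication clusters the origin is the median
  origin interval over the modal origin chromosome.
* Two zero-span breakends have SD defined as 0, so breakend clustering is
  purely positional; their *mate* loci must additionally agree (same
  chromosome, within \(N\,T\) bp) for an edge, otherwise junctions to
  unrelated partners would merge.
* Maximal cliques may share vertices; each signature supports exactly one
  cluster, resolved greedily by clique size, then preliminary score, then
  leftmost position.
* An all-breakend cluster has zero mean span; the consistency terms then
  award their full value when the corresponding deviation is 0, and
  nothing otherwise. The total score is clamped to a minimum of 1,
  respecting the open lower bound of \((0, 100]\).
* Triple windows that reuse a pair already absorbed by an earlier triple
  are skipped: when a read spans two nearby inversions, the normal gap
  between them would otherwise mimic an inverted middle segment.
* Point insertions are evaluated by insertion-point distance (≤ 100 bp)
  together with a reciprocal inserted-length ratio, because literal
  interval overlap is uninformative for zero-reference-span events; for
  benchmarking, interspersed duplications and novel insertions are
  evaluated jointly as insertions, since their distinction depends on
  origin detection that other representations of the same allele lack.

## Known limitations

Genotyping, chromosomal translocations and nested SVs are out of scope
(breakend clusters are consumed only as duplication-origin evidence).
Very large events are limited by read length: an interspersed duplication
whose copy exceeds the typical read length is rarely fully spanned, so at
low coverage its destination may surface only as breakends and go
uncalled. Duplication copies shorter than the minimum alignable segment
arrive as plain insertion signatures and are then indistinguishable from
novel insertions.
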
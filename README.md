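# svclique

Structural variant (SV) calling from long-read alignments. `svclique`
detects deletions, inversions, tandem duplications, interspersed
duplications (with their genomic origin and a cut&paste annotation) and
novel element insertions of ≥ 50 bp from SAM/BAM files of aligned PacBio-
or Nanopore-style reads. It is aimed at users who already have long-read
alignments (including supplementary records for split reads) and want
classified, scored SV calls in BED and VCF form, plus a simulation and
benchmarking harness to validate the caller end to end.

## Method

The pipeline has three stages:

1. **Collect.** Each read is scanned for SV signatures, typed
   `DEL/INS/DUP/INV/TAN/BRK`: large CIGAR gaps inside one alignment
   (*intra-alignment* evidence) and discordant placements/orientations of
   a read's split alignment segments (*inter-alignment* evidence), e.g. a
   strand-flipped middle segment for an inversion, a backward reference
   jump for a tandem duplication, or reference-adjacent flanks with a
   middle segment mapping elsewhere for a duplication with known origin.

2. **Cluster.** Signatures are vertices of a graph with an edge wherever
   their *span-position distance* is below a threshold *T* = 0.7:

   SPD(S₁,S₂) = |span₁−span₂| / max(span₁,span₂) + PD(S₁,S₂)/N,
   PD = min(|B₁−B₂|, |E₁−E₂|, |mid₁−mid₂|), N = 900 bp.

   Clusters are the maximal cliques of this graph (Bron–Kerbosch with
   pivoting) and are scored on (0, 100] from four components: member
   count (≤ 20 per evidence class), an evidence-class bonus (10 intra +
   20 inter), and positional/span consistency terms
   sp = 10·(1−min(1, s_pos/span̄)) and ss = 20·(1−min(1, s_span/span̄)).

3. **Combine.** DEL/INV/TAN clusters are reported directly; DUP clusters
   become interspersed duplications with an origin locus; INS clusters
   pair with nearby breakend clusters (the mate identifies the origin) or
   fall back to novel insertions; duplications whose origin overlaps a
   deletion call are flagged as potential cut&paste insertions.

Calls are written to five BED files and one VCF 4.2 file with symbolic
ALT alleles. A reciprocal-overlap evaluation harness computes
precision/recall curves over score cutoffs against a truth set, and a
fixture simulator generates truth-labelled references, donors and
split/gapped SAM alignments (idealized or with indel-dominated read
errors) so the whole pipeline runs without downloads or an aligner.

## Worked example

Simulate the standard benchmark scenario (a 500 kb genome with 60
homozygous SVs at 6× coverage), call variants, and evaluate:

```sh
Rscript exec/svclique simulate --out-dir demo --seed 7
Rscript exec/svclique call --bam demo/reads.sam --reference demo/reference.fasta --out-dir demo/out
Rscript exec/svclique evaluate --calls demo/out --truth demo/truth.bed
```

The `call` step logs per-stage counts:

```
segments: 732 from 338 reads
signatures: BRK=42 DEL=109 DUP=80 INS=26 INV=51 TAN=67
clusters: 84
calls: deletion=20 interspersed_duplication=15 inversion=10 novel_insertion=5 tandem_duplication=10
```

732 alignment records from 338 reads produced 375 signatures; clustering
merged them into 84 clusters, of which the 60 non-breakend ones became
calls — here exactly the implanted 20/10/10/15/5 per class. The
`evaluate` step prints the precision/recall table across score cutoffs
(at 50% reciprocal overlap):

```
cutoff  n_calls  tp  fp  fn  precision  recall
  0     60       60  0   0   1          1.00000
 10     60       60  0   0   1          1.00000
 ...
```

Every implanted variant was recovered with the correct class and no
false positives at this seed. The same loop is available in R via
`simulate_dataset()`, `run_pipeline()` and `precision_recall_curve()`.

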
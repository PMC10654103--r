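---
title: "Proteomic equivalence clustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic equivalence clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peqclust)
```

## The model

A phage genome is represented as a multiset of gene records, each a
(pham, translation) pair: the pham is a family of related phage proteins
assembled upstream (the package consumes the assembler's three-column
genome–pham–translation TSV and does no gene calling or family assembly
itself), and the translation is the protein's amino-acid sequence. Two
genomes are compared entirely through this representation.

The default similarity, the proteomic equivalence quotient, is
`PEQ = AF × AAI`. AF is the fraction of total protein length (summed over
both genomes) that sits in shared phams, paralogous copies included; AAI
is the length-weighted average percent identity over orthologous protein
pairs drawn from the shared phams, computed from Needleman–Wunsch global
alignments. The product couples the two failure modes of simpler
metrics: gene-content measures (JC, GCS, POCP) saturate for genomes that
share families of long-diverged genes, while identity measures (AAI
alone) are blind to how much of the genome is shared at all. A PEQ of 1
requires both complete gene sharing and perfect amino-acid identity; a
PEQ of 0 means no shared phams — which, given the detection floor of
upstream pham assembly (roughly 15% global amino-acid identity), is the
operational meaning of "unrelated".

### Alignment conventions

Alignments use BLOSUM62 with affine gap penalties 11/1 (opening /
extension). Three conventions are fixed explicitly because "−11/−1"
alone does not determine them:

* a gap of length L costs `gap_open + (L − 1) × gap_extend`, i.e. the
  opening column carries the opening penalty (the convention of the
  C alignment libraries commonly bound for this purpose; the Biostrings
  parameterisation maps onto it with `gapOpening = gap_open − gap_extend`,
  which the test suite uses as an independent score cross-check);
* percent identity divides the count of identical aligned residue pairs
  by the **total number of alignment columns, gap columns included**.
  The choice is conservative — it can only deflate identity — and is the
  usual convention for reporting global-alignment identity. It is a
  recorded package decision, not something the metric's name dictates;
* equal-scoring tracebacks are resolved deterministically, preferring
  the diagonal (aligned) move over a gap in the second sequence over a
  gap in the first, so identity counts are reproducible across platforms.

The ambiguity residue X participates with the substitution scores of the
matrix's X row; silently dropping such residues would corrupt the
lengths AF depends on. Translations are uppercased on ingest and
terminal stop/gap characters stripped; internal ones are rejected as
corrupt input rather than repaired.

### Ortholog pairing and AAI weights

Published formulations leave paralog pairing and the "length-weighted"
average unspecified. The package pairs each shared pham's copies
positionally after sorting both genomes' copies by length, descending
(ties keep input order), up to the smaller copy count; unpaired copies
still count as conserved length in AF but take no part in AAI. Each
pair's weight is the sum of its two unaligned lengths, which keeps AAI
symmetric in the genome arguments. These are package decisions; any
fixed, symmetric convention would serve, and the chosen one favours
pairing the full-length representatives of a family.

## The clustering procedure

Clustering is greedy threshold agglomeration: all unordered pairs at or
above the threshold are processed in descending similarity (ties broken
lexicographically on (min id, max id) — the descending-order rule leaves
tie order undefined, and determinism is a hard requirement). A pair of
unassigned genomes founds a cluster; an unassigned genome joins a
cluster when the linkage criterion holds against every current member
(complete: minimum ≥ threshold; average: mean ≥ threshold; single:
always, since the linking pair qualifies); two clusters merge when the
criterion holds over all cross-pairs. Whether already-formed clusters
may merge mid-pass is a design point the descending-order description
leaves open; the package allows it, under the same linkage test, which
makes single linkage provably equal to connected components of the
thresholded similarity graph (asserted against an independent graph
oracle in the tests).

The two-iteration workflow exists because one-shot clustering at a
permissive threshold lets single mosaic genomes bridge otherwise
distinct clusters. Iteration one (complete linkage, default threshold
0.75) produces homogeneous pre-groups; each is represented by its
medoid, the member with the highest mean similarity to the rest (ties:
lexicographically smallest id). Iteration two clusters the medoids
(average linkage, default 0.25), and every pre-group follows its medoid
wholesale — re-testing non-medoid members would defeat the purpose of
choosing a robust representative. Multi-genome clusters are named
1, 2, 3, … by descending size (ties by smallest member id); singletons
are named after their genome, matching the presentation convention of
curated phage collections.

Subclustering applies the same agglomeration (single linkage, default
threshold 0.60) within each cluster of at least `subcluster_min_size`
members. The floor defaults to 5: subdividing smaller clusters produces
taxonomic noise rather than structure. No single subcluster threshold
suits every cluster — real clusters differ widely in internal
heterogeneity — which is why `subcluster_count_sweep()` exposes the
threshold–count relationship per linkage for exploration rather than
the package hard-coding more than a starting default.

Thresholds are fractions internally; the command-line wrapper accepts
percentages and converts once at parse time, avoiding double-scaling
bugs between the two conventions seen in practice.

## Partition evaluation

Two partitions over the same genomes are compared by classifying every
unordered pair: co-clustered in both (TP), reference only (FN),
prediction only (FP), neither (TN). Precision `tp/(tp+fp)`, sensitivity
`tp/(tp+fn)` and the Matthews correlation coefficient
`(tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))` follow. Counts are
kept exact (they reach millions for thousand-genome corpora; integers
below 2^53 are exact in doubles, and the MCC denominator is computed as
a product of square roots to avoid overflowing the four-way product).
Undefined ratios — an all-singleton partition has no positive pairs —
are surfaced as `NA` with a warning, never silently zeroed.

The per-cluster decomposition attributes each cross-cluster pair half
to each of the two reference clusters it touches. This half-weighting
is the unique convention under which the per-row values both sum
exactly to the global counts and give the natural closed forms (an
exactly recovered cluster of size s among N genomes shows
`tn = s(N − s)/2`). Scalar statistics are reported truncated — not
rounded — to three decimals, a presentation rule only.

## The synthetic corpus generator

`generate_table()` emulates, at desk scale, a curated phage corpus with
planted structure: each cluster has a private core pham pool carried by
every member (default 80% of the 20 genes per genome), a small draw
from a global pool shared across clusters emulates horizontal exchange
(default 10%), the rest is genome-private; translations diverge from
each pham's ancestral sequence by independent per-residue substitution
(default 5%), and occasional paralogs (default 5% per gene) are
truncated, re-mutated copies so alignments exercise gaps. Defaults were
chosen once as a realistic scaled-down regime: they put intra-cluster
PEQ near 0.75 and inter-cluster PEQ below 0.1, i.e. the same clean
separation around the 0.25 cluster threshold that motivates the default
thresholds on real corpora, with three clusters of six genomes keeping
a full matrix build (153 pairs, a few thousand alignments) under a few
seconds.

Substitutions are uniform over the 19 other residues with no indels, so
the expected identity between two cluster-mates is analytically
`≈ (1 − rate)²`, which the trend tests exploit. What the generator does
*not* emulate: gene-order mosaicism, indel evolution, annotation
artefacts (missed ORFs, variant start codons), or the long tail of
cluster-size imbalance in real collections. Passing recovery tests
therefore demonstrate correctness of the machinery under clean planted
structure, not robustness to every idiosyncrasy of real phage data.

## Numerical and degenerate-input choices

* Similarities are validated to be symmetric, unit-diagonal and within
  [0, 1] before clustering; non-finite entries are hard errors.
* An empty table, an empty translation, or a residue outside the
  20-standard + X alphabet is an error at parse time with a 1-based
  line number; a single header line is auto-detected (by its third
  field not being a valid residue string) and tolerated, since upstream
  exporters differ on emitting one.
* A single-genome input yields one singleton cluster named after the
  genome; thresholds are accepted on (0, 1] only.
* Matrix construction is embarrassingly parallel over pairs and
  bit-identical regardless of worker count; the on-disk pair cache is
  keyed by metric and alignment parameters so a cached score is never
  reused under different scoring.

## Problem sizes used in the tests

The suite runs entirely on generated or packaged miniature data: the
6-genome packaged corpus, random sequence pairs up to length 30 against
a brute-force DP oracle (plus length ~60 for cross-library score
checks), 18-genome synthetic corpora for matrix/clustering properties,
and 20 seeds of planted-partition recovery. The published-scale
pair-counting arithmetic (2,121 genomes) is pure integer work on
constructed label vectors and runs in milliseconds; full-corpus
clustering of thousands of real genomes is supported by the same code
paths but is not exercised in the test suite.

## Known limitations

* AAI pairing of paralogs is heuristic (length-sorted positional); a
  score-optimal assignment would require all-vs-all alignment within
  each shared pham.
* The greedy agglomeration is order-dependent by design (that is the
  published procedure); it is deterministic but not equivalent to
  dendrogram-based hierarchical clustering with a cut.
* Average- and complete-linkage cluster counts are not theoretically
  monotone in the threshold for adversarial matrices, though they are
  on the fixtures tested; single linkage is monotone by the components
  equivalence.
* No nucleotide-level metric is provided; validation against
  nucleotide identity is outside the package's scope.
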
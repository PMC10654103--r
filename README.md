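# peqclust

Proteome-based similarity and clustering for phage genomes.

## The problem

Phage genomes are pervasively mosaic: horizontal genetic exchange means
whole-genome nucleotide comparisons are expensive and often misleading for
distantly related phages. `peqclust` works instead from a genome's
proteome, described as a table mapping each genome to its gene phamilies
("phams" — families of related phage proteins assembled upstream by tools
such as MMseqs2-based pham builders) and their amino-acid translations.
It is aimed at phage genomicists who want to assort hundreds to thousands
of genomes into clusters and subclusters of related phages, and to audit
those groupings quantitatively.

## The metrics

For a pair of genomes, with pham-set sizes `P1`, `P2`, shared phams `P_S`,
protein counts `T1`, `T2`, conserved (shared-pham) copies `C1`, `C2`,
summed protein lengths `L_T1`, `L_T2` and summed conserved lengths
`L_C1`, `L_C2`:

* **JC** (Jaccard coefficient) = `|intersection| / |union|` of pham sets
* **GCS** (gene content similarity) = `2 P_S / (P1 + P2)`
* **POCP** (percentage of conserved proteins) = `(C1 + C2) / (T1 + T2)`;
  equals GCS on paralog-free genomes
* **AF** (alignment fraction) = `(L_C1 + L_C2) / (L_T1 + L_T2)`
* **AAI** (average amino acid identity): length-weighted mean percent
  identity over orthologous protein pairs, from Needleman–Wunsch global
  alignments (BLOSUM62, affine gaps −11/−1)
* **PEQ** (proteomic equivalence quotient) = `AF × AAI` — the default; 1.0
  means every gene is shared at 100% identity, 0 means no shared phams

Distance is `1 − similarity`. Clustering is a greedy threshold
agglomeration processing pairs from most to least similar, run in two
iterations: complete linkage at PEQ ≥ 75% builds homogeneous pre-groups,
their medoids are clustered by average linkage at PEQ ≥ 25%, and each
pre-group follows its medoid. Non-singleton clusters can be subclustered
by single linkage at PEQ ≥ 60%. Predicted partitions are scored against
reference assignments with unordered-pair confusion counts, precision,
sensitivity, and the Matthews correlation coefficient (MCC).

## Worked example

Using the packaged 6-genome miniature corpus (two related groups plus one
unrelated singleton):

```r
library(peqclust)
tsv <- system.file("extdata", "minicorpus.tsv", package = "peqclust")
corpus <- parse_pham_tsv(tsv)
corpus
#> <pham_table> 6 genomes, 10 phams, 20 genes

m <- build_matrix(corpus, metric = "peq")
round(m, 3)
#>        AlphaA AlphaB AlphaC BetaA BetaB Solo
#> AlphaA  1.000  0.754  0.842     0     0    0
#> AlphaB  0.754  1.000  0.842     0     0    0
#> AlphaC  0.842  0.842  1.000     0     0    0
#> BetaA   0.000  0.000  0.000     1     1    0
#> BetaB   0.000  0.000  0.000     1     1    0
#> Solo    0.000  0.000  0.000     0     0    1

two_step_cluster(m, clustering_config())
#> <genome_partition> 6 genomes in 3 clusters (1 singletons)
```

The three `Alpha` genomes share 3 of their 4–5 phams at near-identity
(e.g. AlphaA vs AlphaC: AF 0.860, AAI 0.980, PEQ 0.84), so they form
cluster `1`; the `Beta` pair forms cluster `2` (PEQ 1.0 — all genes
shared, identical translations); `Solo` shares no phams with anyone and
remains a singleton named after itself. The full pipeline — matrix,
partition, per-cluster matrices, HTML heatmaps, evaluation report, log —
runs as

```r
run_pipeline(tsv, "out/", reference = NULL)
```

or from a shell via the thin wrapper:

```sh
Rscript inst/scripts/peqclust input.tsv --outdir out --cluster-threshold 25 --cpus 4
```

## Package layout

* `R/` — table parsing, global alignment (Rcpp core), the six metrics,
  greedy clustering, partition evaluation, pipeline/reports, synthetic
  corpus generator
* `vignettes/proteomic-equivalence-clustering.Rmd` — methods and design
  notes
* `tests/testthat/` — unit, property, and acceptance tests with
  independent oracles (plain-R alignment DP, brute-force pair counting,
  graph components)
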
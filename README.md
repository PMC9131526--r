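# genarch — genome architecture decomposition

genarch decomposes a genome assembly into architectural domains: conserved
cores, subtelomeric multigene-family arrays, telomere-adjacent repeat
blocks, repeat bands, gene deserts. It is aimed at anyone with a
chromosome-scale assembly — parasitology and comparative-genomics groups
especially — who wants a data-driven, reproducible segmentation of their
chromosomes instead of arbitrary cutoffs.

## Method

The genome is tiled into fixed-size non-overlapping windows (default
5 kb). For each window *w* a feature vector is computed from the sequence
alone — GC%, AT/GC skew (G−C)/(G+C), CpG frequency, stop-codon frequency,
telomeric/CAG motif densities, k-mer spectrum deviation
‖f<sub>w</sub> − f<sub>genome</sub>‖₂ for k ∈ {3, 4}, N%, low-complexity
and tandem-repeat fractions, and a mappability depth in [0, 10] in which a
segment present in *m* exact copies scores ≈ 10/*m* — optionally extended
with gene-annotation densities from a GFF3 and any user bedgraph tracks.
Features are min-max scaled to [0, 1], embedded in 2-D with UMAP
(*n* neighbours) and clustered with HDBSCAN (minimum cluster size *c*,
label −1 = unclassified). Each cluster is characterised by one-sided
two-sample Kolmogorov–Smirnov tests per feature (D⁺ = values higher than
the rest of the genome, D⁻ = lower, both = dispersed; significance at
p ≤ 1e−20), and cluster adjacency along chromosomes is tested with
Fisher's exact test under Benjamini–Hochberg correction. Labels map back
to chromosomes as a BED track.

A synthetic-genome module plants known architecture (segment-wise GC,
motif arrays, tandem duplications, gene densities, truth labels) so the
whole pipeline is testable end to end; recovery is scored with the
adjusted Rand index.

## Worked example

```r
library(genarch)

sim  <- simulate_genome(parasite_preset(), seed = 1)   # 3 chromosomes, 3 Mb
fm   <- run_extract(sim$assembly, config = run_config(seed = 1))
tab  <- run_sweep(fm, config = run_config(seed = 1))
sel  <- attr(tab, "recommended")
res  <- run_cluster(fm, n = sel$n, c = sel$c,
                    config = run_config(seed = 1), outdir = "out")
score_recovery(res$labels, sim$truth, fm$grid)$ari
```

On this run the sweep's recommended cell (n = 20, c = 50) prints

```
3 clusters, 0.00% unclassified, silhouette 0.877
```

and the recovery score is `ari = 1`: the three planted domain types —
AT-rich core (GC ≈ 19.0%, mappability ≈ 10), duplicated family arrays
(mappability ≈ 2.0) and telomere-adjacent repeat blocks (GC ≈ 33.6%,
high telomeric motif density) — are recovered exactly. `out/` then
contains the cluster BED, KS and junction TSVs, the heatmap table, the
embedding, the resolved configuration and static figures (embedding
scatter, chromosome cluster paint, feature heatmap).

A thin CLI wraps the same functions:

```sh
exec/genarch simulate --out sim --seed 1
exec/genarch extract  --fasta sim/genome.fasta --gff3 sim/genes.gff3 --out feats
exec/genarch sweep    --matrix feats/feature_matrix.tsv --out sweep
exec/genarch cluster  --matrix feats/feature_matrix.tsv --n 20 --c 50 --out run
exec/genarch haars    --proteins proteome.fasta --out haars.tsv
```

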
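---
title: "Decomposing genome architecture from windowed sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing genome architecture from windowed sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Chromosomes are not homogeneous: parasite genomes in particular are built
from recognisable linear domains — conserved gene-dense cores, subtelomeric
arrays of variant multigene families, telomere-adjacent repeat blocks,
repeat bands, gene deserts. genarch makes these domains visible from a
genome assembly alone. The procedure is deliberately simple and fully
unsupervised:

1. **Windows.** Every scaffold is partitioned into contiguous,
   non-overlapping windows of fixed size (default 5 kb, roughly one gene in
   a compact parasite genome). The trailing window of a scaffold is kept
   even when short, so windows tile each scaffold exactly and every base
   belongs to exactly one window. Non-overlapping windows mean every part
   of the genome receives exactly one cluster label.
2. **Features.** Per window we compute sequence-derived signals: GC
   percentage, AT and GC skew, CpG dinucleotide frequency, stop-codon
   frequency (TAA/TAG/TGA, forward strand, all frames), telomeric and CAG
   motif frequencies (reverse complement included), k-mer spectrum
   deviation for k = 3 and 4, N percentage, a low-complexity fraction, a
   tandem-repeat fraction and a mappability depth (details below). With a
   GFF3 annotation, per-window gene densities by type and mean gene /
   exon / intron statistics are added; arbitrary bedgraph tracks (ChIP
   log-ratios, repeat densities, ...) can be re-binned onto the grid and
   appended.
3. **Scaling and embedding.** Features are min-max scaled to [0, 1]
   per column and embedded in two dimensions with UMAP; the embedding is
   clustered with HDBSCAN, which labels low-density windows `-1`
   (unclassified) rather than forcing them into a cluster.
4. **Characterisation.** Each cluster is described by two one-sided
   two-sample Kolmogorov–Smirnov tests per feature (cluster windows versus
   all other windows), giving D+ (values higher), D− (values lower) or
   both (distribution more dispersed). Cluster adjacency along chromosomes
   is tested for enrichment with Fisher's exact test and
   Benjamini–Hochberg correction. Labels are written back as a BED track,
   so the architecture can be inspected in a genome browser.

## Counting rules

A motif, k-mer or codon is counted only when it lies wholly inside a
window; a match broken by a window border is counted in neither window.
This follows directly from computing features on extracted window
sequences and is property-tested: counting on the concatenation of two
windows exceeds the per-window sums by exactly the border-straddling
matches.

Frequency denominators use the window's *effective length* (its A/C/G/T
count), so N runs do not dilute frequencies: CpG uses effective length − 1
dinucleotide positions, stop codons effective length − 2, motif counts are
per 100 bp of effective length. Degenerate windows are never dropped:
all-N windows report GC 0, skews 0, frequencies 0, and carry N
percentage 100, so downstream stages always see the full grid.

## Bespoke surrogate features

Three features replace external tools with simple deterministic
definitions; they are deliberately named for what they compute rather
than after any tool, because they are approximations:

* **Low-complexity fraction** — a DUST-style triplet score: 64 bp scan
  windows every 16 bp are scored `10 * sum c(c−1)/2 / (T−1)` over their
  triplet counts and masked whole above a score of 20. Homopolymers score
  ~300 and mask fully; random sequence scores ~5 and stays unmasked. The
  16 bp step trades boundary resolution (at most one scan window, 64 bp)
  for speed.
* **Tandem repeat fraction** — the fraction of the window covered by
  maximal *perfect* tandem runs with unit sizes 1–12 (positions matching
  the base one unit earlier, sustained so the repeated region spans at
  least twice the unit). Imperfect repeats are not chased; on AT-rich
  genomes the unit-1/2 runs give a high baseline, which min-max scaling
  renders comparable across windows.
* **Mappability depth** — a deterministic stand-in for mapping simulated
  reads: error-free 150 bp fragments are tiled every 15 bp (fold 10), and
  each contributes weight 1/m over the bases it covers, where m is the
  number of exact full-length match loci in the assembly on either strand
  (counted by rolling 64-bit hashing). Unique sequence reaches depth
  ~10; a segment present in m copies drops to ~10/m, so multigene-family
  arrays stand out. Fragments containing N are skipped, and scaffolds
  shorter than a fragment contribute nothing. Unlike read simulation it
  has no error model and only detects exact duplications.

The k-mer deviation needs a distance definition; we use the Euclidean
distance between the window's normalised k-mer frequency vector and the
genome-wide profile (computed once, forward strand, N-containing k-mers
skipped). Euclidean is symmetric, bounded and cheap; the operation is a
single function so L1 or cosine alternatives could be swapped in without
touching anything else.

## Clustering choices

UMAP's `n_neighbours` (n) and HDBSCAN's `min_cluster_size` (c) dominate
the result: small n fragments the data, large n consolidates it, and c
sets the smallest domain that can emerge as its own cluster.
`sweep_clusterings()` runs the full n x c grid (default {5, 10, 15, 20} x
{50, 100, 200, 500}) and scores each cell with the silhouette,
Davies–Bouldin and Calinski–Harabasz metrics, computed on the embedding
coordinates of classified windows only — the embedding is what HDBSCAN
actually clusters, and unclassified windows have no cluster to cohere
with. Note HDBSCAN's `min_samples` follows its library default (equal to
c), so large c on few windows conservatively labels everything noise;
such sweep cells simply score as empty.

`select_params()` ranks cells by percentage of unclassified windows
first, silhouette second, cluster count third — a clustering that
accounts for the whole genome but separates slightly less cleanly is
preferred over a tidy clustering that discards many windows. The
selection is advisory: the final run takes an explicit (n, c), keeping
the parameter choice a deliberate, recorded decision.

`min_dist` defaults to 0.1 and the metric is Euclidean; a fixed seed
(default 42) is part of the configuration and recorded next to every
output, making runs bit-reproducible. The embedding runs through the
umap-learn and scikit-learn libraries via a bundled Python worker; with a
fixed seed UMAP runs single-threaded and deterministically, and HDBSCAN
is deterministic.

Silhouette could alternatively be computed on the scaled feature matrix;
we compute it in embedding space because that is the space in which the
clusters exist, and the sweep table records everything needed to
recompute it elsewhere.

## Cluster statistics

The KS characterisation runs both one-sided directions per (cluster,
feature) pair at a stringent default threshold of 1e-20, matching the
conventional significance icons (`^` higher, `v` lower, `-` dispersed) on
the cluster heatmap; p-values are asymptotic
(`exp(-2 D^2 mn/(m+n))`), appropriate at hundreds of windows. For small
samples an exact tie-free p-value is available via lattice-path counting
and is verified against full permutation enumeration in the tests.
Unclassified windows are genomic windows like any other, so they
participate in the "rest" sample of every test but never form a cluster
row.

Junction enrichment counts the unordered label pair of every pair of
adjacent windows within a scaffold (self-pairs included; scaffold
boundaries contribute no junction), compares each pair's count against
the expectation under the marginal label frequencies with Fisher's exact
test, and corrects across pairs with Benjamini–Hochberg. Because
architectural domains are contiguous, same-cluster junctions are
massively enriched in any real decomposition — a useful sanity check.

## The synthetic genome generator

`simulate_genome()` plants architecture explicitly so that every stage of
the pipeline can be validated against known truth. Segments are
concatenated per chromosome; each segment draws its background i.i.d. at
a target GC, may receive verbatim tandem arrays of a motif and/or a
tandemly duplicated unit, and places genes uniformly at a stated density
with 1–4 exons. Every base carries its segment's truth label, and
`score_recovery()` compares window clusterings against the majority truth
label per window with the adjusted Rand index (unclassified windows count
as their own class, so discarding windows is penalised).

The `parasite_preset()` mirrors a *Plasmodium*-like architecture: three
chromosomes of 1.2, 1.0 and 0.8 Mb, each with 50 kb telomere-adjacent
repeat blocks built from ~2000 copies of TTTAGGG on a GC 0.30 background
(realised GC ≈ 33%), 100 kb multigene-family arrays made of a 16 kb unit
in 6 tandem copies at GC 0.22 with 3 genes per 10 kb (mappability ≈
10/6 ≈ 1.7), and an AT-rich core at GC 0.19 with 2 genes per 10 kb.
The family segments are wall-to-wall duplicated array because that is
what they are meant to emulate — regions dominated by near-identical
paralogues — and because their truth label must describe their actual
content. The contrasts (GC 19 vs 22 vs 33%, mappability 10 vs 1.7,
telomeric motif density) are the same axes that separate real parasite
genome domains.

What the i.i.d. model does *not* emulate: codon structure, isochores,
transposable elements, imperfect/diverged repeats, or realistic gene
sequences — genes affect only the annotation tracks, not the sequence
itself. Passing the planted-recovery test therefore demonstrates that
the pipeline machinery recovers strong compositional/uniqueness contrasts
at realistic effect sizes; it does not certify performance on genomes
whose architecture is written in features the generator does not plant.

## Problem sizes and numerical conventions

The test-suite and acceptance runs use the 3 Mb preset (600 windows of
5 kb) and a 2 Mb fixture for mappability; these sizes exercise every code
path at full feature resolution while keeping a complete run in tens of
seconds on one CPU. Feature extraction scales linearly in genome size
(the mappability hash pass dominates); the window-merging operation
(`merge_windows()`, length-weighted means over runs of fine windows,
then re-scaling) supports the coarse-resolution workflow used for large
genomes, where 5 kb features are merged into 50 kb bins before
clustering. Merging acts on raw values and re-scales afterwards, so a
merged matrix equals the matrix one would have extracted directly at the
coarse size for additive features (verified for GC in the tests).

Other conventions: min-max scaling maps constant columns to all-0 (stated
explicitly, not inherited from any library); coordinates are 0-based
half-open everywhere internally and in bedgraph/BED output; TSV output is
written at full double precision and round-trips losslessly; feature
columns are never dropped automatically — exclusion is an explicit
configuration list (e.g. dropping the CAG track for genomes where it was
never relevant).

## Known limitations

* Repeat-family, orthology and retrotransposon features are out of scope
  as computations; they enter only as precomputed bedgraph tracks.
* The UMAP/HDBSCAN stage needs a Python interpreter with umap-learn and
  scikit-learn on the PATH (a deliberate use of the reference
  implementations of both algorithms rather than a reimplementation).
* One-sided KS asymptotic p-values are anti-conservative below ~30
  windows per cluster; with `min_cluster_size` ≥ 50 this does not arise
  in practice.
* The mappability surrogate sees only exact duplications; diverged
  repeats require an external track.
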
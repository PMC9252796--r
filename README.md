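# compbin

Reference-free, composition-based binning of metagenomic sequences, with a
two-class differential density analysis on the embedding.

## What it does and who it is for

Metagenomic assembly and long-read metagenome sequencing produce thousands
of anonymous contigs or reads from a mixed community. When reference
databases are incomplete — new environments, novel taxa — the standard
recourse is *binning*: grouping sequences that likely come from the same
genome. `compbin` is for researchers who need reference-free bins from a
**single** sample, where coverage-based binning is not applicable, and who
additionally want to *compare* two sample classes (e.g. two sequencing
technologies, case vs control) without references or coverage profiles.

The pipeline:

1. **Profiles** — each sequence of length ≥ k becomes a normalized
   canonical k-mer frequency vector (k = 4 or 5). The canonical form of a
   k-mer is min(w, revcomp(w)); collapsing strands gives 136 features for
   k = 4 and 512 for k = 5. Windows containing N are skipped.
2. **Embedding** — profiles (optionally PCA-compressed) are reduced to 2D
   with UMAP (default), t-SNE, or PCA; fixed seeds give identical
   coordinates on rerun.
3. **Clustering** — DBSCAN, HDBSCAN (default, `min_cluster_size = 10`),
   k-means, or spectral clustering on the embedding yields candidate bins;
   density methods may leave noise points (label 0).
4. **Assignment** — a ridge multinomial classifier trained on the k-mer
   profiles of the clustered subset assigns noise points, members of
   too-small clusters, and below-filter sequences to bins when its class
   probability reaches the confidence threshold (default 0.5).
5. **Differential density** (optional) — for a two-class labeling, each
   class gets a Gaussian KDE over the shared embedding,

   f̂_c(x, y) = (1/n_c) Σ_{i∈c} (2π h_x h_y)⁻¹ exp(−(x−x_i)²/2h_x² − (y−y_i)²/2h_y²),

   with shared Scott's-rule bandwidths (h_i = σ_i·n^(−1/6)) and a shared
   padded grid; the surface f̂_A − f̂_B and per-cluster mean/sum scores
   highlight class-specific regions of composition space.

A fully deterministic Markov-chain community simulator
(`community_spec()`, `generate_community()`,
`generate_differential_pair()`) provides ground-truthed data for every
stage.

## Worked example

Simulate a 5-genome community in which genome 5 occurs only in class A,
then bin and compare the classes (the same calls are available in R via
`run_pipeline()` / `density_difference()`):

```sh
Rscript inst/cli/compbin simulate --out demo --n-genomes 5 --fragments 200 \
    --abundance-a 0.4,0.15,0.15,0.15,0.15 --abundance-b 0.25,0.25,0.25,0.25,0 --seed 7
Rscript inst/cli/compbin bin --input demo/community.fasta --out demo_out \
    --classes demo/classes.tsv --seed 7
```

```
read 400 sequence(s); 400 pass the 500 bp length filter
embedded 400 sequence(s) with umap
found 6 cluster(s), 0 noise point(s)
assigned: 400 by cluster, 0 by classifier, 0 unassigned
```

`demo_out/` now holds `assignment.tsv` (bin, provenance, confidence,
length, GC per sequence), `embedding.tsv`, `clusters.tsv`,
`bin_summary.tsv` (per-bin size, total bp, N50, mean GC, fraction of
sequences, and a minor-bin flag for bins under 1% of sequences), the
differential-density grid and per-cluster table, and `manifest.json` — the
exact parameters and seed needed to reproduce the run byte-for-byte.

The per-cluster differential table (also printed by `compbin diff`):

```
  cluster n_A n_B    mean_diff    sum_diff
1       1  80  50  0.002798569  0.36381398
2       2  30  50 -0.001338221 -0.10705769
3       3  30  50 -0.001394411 -0.11155288
4       4  25  39 -0.001733766 -0.11096103
5       5  30   0  0.003138312  0.09414937
6       6   5  11 -0.001642958 -0.02628732
```

Cluster 5 is the planted signal: all 30 of its members are class A
(`n_B = 0`) and its `mean_diff` is the largest positive score — class A's
density exceeds class B's everywhere that cluster lives. Negative scores
mark regions relatively enriched in class B. Because each class density is
normalized by its own sequence count, these scores measure distributional
shift, not absolute abundance; `n_A`/`n_B` are reported so you can rescale.

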
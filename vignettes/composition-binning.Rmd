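---
title: "Composition-based binning and differential density analysis with compbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based binning and differential density analysis with compbin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compbin)
```

## The problem

Metagenomic assemblies and long-read runs deliver thousands of anonymous
sequences from a mixed community. When reference databases cannot resolve
them, *binning* groups sequences that plausibly originate from the same
genome. compbin implements reference-free, composition-based binning: the
only signal used is each sequence's own k-mer spectrum, which is
approximately conserved along a genome and differs between taxa. Coverage
profiles — the other common binning signal — require multiple samples or
read mappings and are deliberately out of scope.

The pipeline is: normalized k-mer profiles → optional linear compression →
2D embedding → density-based clustering → a classifier trained on the
clustered subset assigns everything else. On top of it sits a two-class
comparative analysis: per-class Gaussian kernel densities over the shared
embedding and their difference surface.

## Feature space: canonical k-mer profiles

For k ∈ {4, 5} every window of length k that contains no N is counted
toward the *canonical* form of its k-mer — the lexicographic minimum of the
k-mer and its reverse complement. Collapsing is essential because the
strand of a contig or read is arbitrary; it reduces the feature space from
4^k to 136 (k = 4; 16 reverse-complement palindromes plus 120 pairs) or 512
(k = 5; odd k has no palindromes). Counts are divided by the number of
valid windows, so every profile row sums to 1 and sequences of different
lengths are comparable. Windows containing N are skipped rather than
randomized — randomization would break run-to-run determinism — and a
sequence whose windows all contain N is rejected with an error naming it.

Frequency normalization is the minimal reading of "normalized profile";
centered log-ratio or rank transforms would be defensible alternatives but
add parameters without a clear benefit at these k values. The default is
k = 5, the richer space; k = 4 halves memory and is adequate for well
separated communities.

## Embedding

Profiles (optionally PCA-compressed to `compress_dims = 50` components;
compression switches on automatically above 5000 sequences, where the
nonlinear embeddings become the bottleneck) are reduced to 2D by one of:

* **umap** (default) — `uwot::umap`, run single-threaded with
  single-threaded SGD so that a fixed seed gives bitwise-reproducible
  coordinates; `n_neighbors` is capped at n − 1 for small inputs.
* **tsne** — `Rtsne`, with perplexity capped at ⌊(n − 1)/3⌋ when the
  backend default (30) is infeasible.
* **pca** — the first two principal components; fully deterministic, no
  tuning, and the always-available baseline. Component signs are fixed by
  the largest-loading convention so reruns are identical.

Hyperparameters follow each backend's published defaults; the distance
metric on profiles is Euclidean. Other embedding algorithms (Fit-SNE,
PHATE, TriMap) are interchangeable in principle but not bundled; the
`embed_2d` dispatch would accommodate them.

## Clustering

Clustering operates on the 2D embedding — for all methods, including
spectral clustering, so the methods are directly comparable on one view of
the data. Four backends: `dbscan` and `hdbscan` (authored in this package:
DBSCAN as the classic region-growing algorithm, HDBSCAN as
mutual-reachability MST → single-linkage hierarchy → condensed tree →
excess-of-mass selection), `kmeans` (`stats::kmeans`, 10 restarts) and
`spectral` (`kernlab::specc`, with a median-pairwise-distance RBF width
because the automatic estimator is unstable on well-separated embeddings).

The default is `hdbscan` with `min_cluster_size = 10`: density-based, needs
no cluster count, and leaves ambiguous points as noise (label 0) rather
than forcing them into a bin — those points are exactly what the classifier
stage is for. Labels are renumbered 1..K by decreasing size with ties
broken by the smallest member id, so cluster 1 is always the largest and
output is stable under row permutation.

## Semi-supervised assignment

The clustered, non-noise sequences (minus clusters with fewer than 5
members, which are too small to learn from) become the training subset of a
ridge-regularized multinomial logistic classifier (`glmnet`, `alpha = 0`)
on the k-mer profiles — not the 2D coordinates, so new or short sequences
can be assigned without re-embedding. The fit uses a warm-started
regularization path down to `lambda.min.ratio = 1e-6` and predicts at the
smallest solved penalty; a cold single-λ multinomial fit is numerically
fragile at hundreds of features and many classes, and heavier penalties
squash the class probabilities toward uniform, which starves the
confidence threshold.

Every sequence then receives a bin: clustered sequences keep their cluster
(provenance `cluster`; they are never relabeled), everything else — noise
points, members of dropped mini-clusters, and sequences below the length
filter but long enough to profile — gets the classifier's argmax bin if its
probability reaches `confidence_threshold` (default 0.5), else bin 0 with
provenance `unassigned`. Raising the threshold can only shrink the set of
classifier-assigned sequences.

## Differential density between two classes

Given a two-class labeling of the sequences (e.g. two sequencing
technologies, case vs control), compbin estimates a Gaussian kernel density
for each class separately over the *shared* embedding:

$$\hat f_c(x, y) = \frac{1}{n_c}\sum_{i \in c}
  \frac{1}{2\pi h_x h_y}
  \exp\!\left(-\frac{(x - x_i)^2}{2 h_x^2} - \frac{(y - y_i)^2}{2 h_y^2}\right)$$

on a common G×G grid (G ∈ [25, 1000], default 250) with common per-axis
bandwidths — Scott's rule for a 2D sample, $h_i = \sigma_i\, n^{-1/6}$,
computed on the pooled two-class point set so both classes are smoothed
identically. The grid spans the pooled bounding box padded by
4·max(h_x, h_y), which keeps ≥ 99% of each class's probability mass on the
grid. The reported surface is $\hat f_A - \hat f_B$.

Each class is normalized by its own n, so the difference reads as
*distributional shift* — which regions of composition space are relatively
enriched in one class — not absolute abundance; the per-class counts are
reported alongside so users can rescale if they want the absolute reading.
Per-cluster scores evaluate both densities with the exact closed form at
each member point (no grid interpolation, no hull construction) and report
the mean and sum of the pointwise difference: a cluster populated only by
class A gets a strongly positive `mean_diff`. Swapping the class labels
negates every output exactly. No statistical test is attached to these
scores — they are a ranking and visualization device, not an inference
procedure.

## The synthetic community generator

Real mock communities need external data, so testing rests on a generative
model with known truth: each genome is an order-3 Markov chain over
A/C/G/T whose 64 transition rows are drawn independently from a
Dirichlet(α) with α = 0.1. Order 3 makes 4- and 5-mer statistics
genome-identifying *by construction*; small α makes the rows sparse and
the genomes compositionally distinct, emulating the inter-taxon
tetranucleotide divergence that composition binning exploits. Fragments
have lognormal lengths (median 5 kb, σ = 0.5, clipped at 500 bp), matching
the skewed length distributions of assemblies and nanopore runs, with
uniform start positions. A two-class design plants differential signal by
giving some genomes zero abundance in one class.

Defaults (5 genomes of 200 kb, 200 fragments each) are the study
conditions used by the acceptance checks. Everything derives
deterministically from one seed via fixed substreams, so communities are
byte-identical across reruns.

What the generator does *not* emulate: sequencing error, chimeras,
within-genome compositional heterogeneity (GC skew, mobile elements),
shared/homologous regions between genomes, and abundance-coverage
coupling. Passing the recovery tests therefore demonstrates that the
pipeline machinery is correct and well calibrated on clean compositional
signal; it does not certify performance on real assemblies, where bins
blur and completeness must be judged with marker genes.

## Numerical choices and degenerate inputs

* Length filter: ≥ 500 bp (inclusive), a conventional floor below which
  tetranucleotide signal is too noisy to embed; short-but-profileable
  sequences are still binned, via the classifier.
* The KDE grid-size bounds [25, 1000] keep the dense grid evaluation at
  desk scale; the separable-kernel evaluation is exact, matching a naive
  cells×points double loop to ~1e-16.
* Zero-variance axes make Scott's rule degenerate; the user must then give
  an explicit bandwidth. Single-point classes are allowed only with an
  explicit bandwidth.
* Clustering that labels everything noise is an error (with a hint to
  change parameters) rather than an empty result; fewer than 2 trainable
  clusters aborts assignment, since a one-class classifier is meaningless.
* HDBSCAN caps λ = 1/d at 1e12 for zero-distance merges (duplicate
  points), keeping stabilities finite.
* The run manifest records tool version, all parameters, the seed and the
  input digest; a rerun from the manifest reproduces every table
  byte-for-byte. The manifest itself carries a timestamp, so manifest
  equality is checked modulo that field.

## Problem sizes

The test-suite and acceptance workloads use communities of 3–5 genomes ×
60–200 fragments (hundreds to ~1000 sequences), where one full pipeline
run takes seconds; recovery statistics aggregate 5 seeds. These sizes give
stable pass/fail behavior for the properties being checked (ARI, held-out
assignment, differential top-hit) without turning the suite into a
benchmark.

## Known limitations

* Composition alone cannot split closely related genomes; hybrid
  coverage+composition binners will beat it when coverage is available.
* HDBSCAN on UMAP output sometimes over-partitions a genome's cloud into
  sub-clusters. ARI degrades only mildly (sub-clusters stay within-genome)
  but probability mass then splits across sibling bins, which can push
  classifier confidence below threshold; raising `min_cluster_size` or
  lowering `confidence_threshold` counteracts it.
* The O(n²) distance stage of the authored DBSCAN/HDBSCAN is comfortable
  to ~10⁴ embedded sequences; beyond that, prefer `kmeans`.
* Embedding coordinates are reproducible for fixed seed and backend
  versions, not across library upgrades.
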
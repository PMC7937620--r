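---
title: "Image-like network representations for disease-gene classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netimage methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`netimage` treats disease-gene identification as binary image
classification. Every gene of an undirected weighted network is mapped
to an `m × m` matrix `E = A + C`:

* `A` — the adjacency of the node-induced sub-network on the gene and
  its `m − 1` selected neighbours. Neighbours are *not* graph-adjacent
  vertices: they are the most **similar** vertices inside a receptive
  field on the clustering leaf order. Similarity between two genes is
  the reciprocal of the sum of squared differences of their
  adjacency-matrix rows; average-linkage agglomerative clustering on the
  matching distance produces a leaf sequence in which similar genes sit
  close together, and the receptive field of radius `k` is the
  `2k + 1`-wide window around the centre's leaf position. This gives
  every gene — hub or leaf of a scale-free network — a neighbourhood of
  identical size and comparable information content.
* `C` — a diagonal "environment": each selected neighbour contributes
  `t/4`, where `t` is one class code from its (possibly multi-tag)
  disease annotation, resolved against the centre's own tag. Resolution
  uses centroid linkage: the distance between two disease classes is the
  Euclidean distance between the centroids of their member genes'
  adjacency rows. The centre's own diagonal entry is always zero, so a
  gene's image never encodes its own label directly.

The images feed a small convolutional network (two 3×3 convolution
blocks of 16 and 32 filters with ReLU and 2×2 max-pooling, a dense layer
of 64, a sigmoid output; binary cross-entropy, Adam at learning rate
1e-3, at most 100 epochs with early stopping on a held-back validation
split). Flattened row-major to `m²`-vectors, they also feed five
classical learners for comparison. Training is balanced: all
target-class genes are positives and an equal-size seeded sample of
genes annotated with *other* classes serves as negatives.

### Assumptions

* Edge weights are non-negative, symmetric, and comparable within one
  network view (fusion rescales views to `[0, 1]` before averaging).
* Disease classes are encoded as positive integers `1..K`; code 0 means
  "no annotation". Because the class value is `t/4`, the *numeric
  coding* of classes changes the image values. The generator assigns
  the target class code 1 — the conservative choice, since `1/4` is the
  class value closest to the unannotated background of 0.
* Annotation is partial; unannotated genes are usable as neighbours
  (contributing 0 to `C`) but not as training examples.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 21 | image side; `m − 1` neighbours per gene. 21 mirrors a 22-class disease catalogue with one "unclassified" class. |
| `k` | `min(n − 1, 3m)` | receptive-field radius on the leaf order; any value with `m < k < n` is valid. |
| `cap` | `1e12` | similarity assigned to identical adjacency rows, where the reciprocal distance is undefined. Only its ordering relative to finite similarities matters. |
| `use_sqrt` | `FALSE` | reciprocal of the *sum* of squared differences (as defined) vs of its square root; monotone-equivalent for neighbour ranking. |
| `test_fraction` | 0.2 | stratified held-out share in `run_experiment()`. |

## Numerical and procedural choices

* **Leaf order.** `stats::hclust` with average linkage on `1/S`. The
  merge tree is deterministic for a fixed input; no optimal-leaf-order
  post-processing is applied. Note that the left-right *orientation* of
  dendrogram branches — hence the leaf sequence — depends on input
  order, as in every standard agglomerative implementation; the
  dendrogram topology itself is label-invariant and is what the test
  suite asserts under relabeling.
* **Window truncation.** At the ends of the leaf sequence the window is
  extended on the opposite side so the candidate pool always holds
  `min(2k, n − 1)` vertices.
* **Ties.** Neighbour selection breaks similarity ties toward the
  smaller leaf position; class-resolution ties toward the smaller class
  code; threshold scans toward the smaller threshold; tied scores earn
  half credit in AUC (rank-statistic convention).
* **Unannotated centres.** Resolving a neighbour's class needs a
  reference class; when the centre is unannotated (as all evaluation
  genes are, by masking) the target class itself is the reference. This
  keeps positives' images distributionally identical whether or not
  their own tag is visible, because a centre carrying the target class
  uses the same reference.
* **Degenerate inputs.** Self-loops are dropped on read; duplicate
  edges keep the maximum weight; empty classes make centroid distances
  undefined and raise an error only if a tag resolution actually needs
  them.
* **Label masking.** Evaluation genes' tags are hidden *before*
  representation (they also drop out of class centroids), so recovery
  experiments measure generalization, not annotation lookup. Their
  ground-truth labels are kept separately for scoring.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws a degree-corrected planted-partition graph:
power-law expected degrees (density exponent `gamma`, default 2.5) give
the scale-free signature; `K` planted regions with mixing `mu` give
class-correlated topology; the region propensity `(1 − mu)` vs `mu`
scales both the edge probability and the realized edge weight; a
fraction `annotated_frac` of genes carries its region's class, a share
`multitag_prob` of those also the class of the adjacent region they are
most strongly wired to. Additional views jitter weights and rewire a
`view_noise` fraction of edges. The default `mean_degree = 20` matches
the density order of curated PPI networks restricted to a well-covered
gene universe; at substantially sparser settings the row-difference
similarity degenerates into a degree ordering and class structure
becomes invisible to *any* method built on it.

The generator does **not** imitate protein complexes, pathway overlap
structure, annotation ascertainment bias, or the heavy inter-database
correlation of real PPI resources. A green recovery test therefore
establishes that the pipeline extracts planted class-correlated signal
under scale-free degree heterogeneity — not that it would reach any
particular performance on curated human data.

One reading note: the propensity enters both the edge probability and
the weight, so the realized share of edge *weight* crossing regions is
smaller than `mu` itself; `mu` is best read as a propensity scale, not
an exact cross-weight fraction.

## Design decisions that were genuinely open

* **Similarity at zero distance** is capped (configurable) rather than
  infinite; only its rank matters.
* **Neighbour ordering** inside the image follows the leaf sequence
  (centre first); the alternative — similarity rank — would change
  nothing for the CNN up to a fixed permutation but leaf order keeps
  spatially close image cells topologically related.
* **Fusion** computes the neighbourhood field and the environment `C`
  once, on the reference view, and averages only the per-view
  sub-adjacencies; recomputing `C` per view would multiply annotation
  noise without adding information, since the annotation is shared.
* **Class codes** are `1..K` in sorted class-name order with the target
  class at 1 in the generator (see Assumptions).
* **Classical learners** standardize features on the training split;
  the CNN receives raw images. Mixing edge-weight and class-value
  scales hurts kernel methods, while the CNN's first convolution learns
  its own scaling.
* **SVM hyperparameters**: Gaussian bandwidth by the median heuristic,
  polynomial degree 3, `C = 1`; SMO with Platt-scaled probabilities.
  Extra-trees: 100 trees, `√p` features, one uniform threshold per
  candidate feature.

## Known limitations

* The held-out sets of the synthetic recovery experiments are small
  (tens of genes), so single-seed AUCs carry sampling error of roughly
  ±0.1; conclusions are drawn from multi-seed means.
* At the reference synthetic configuration (n = 800, K = 8, mu = 0.2,
  30 % annotated) the receptive fields are only ~50 % region-pure —
  the row-difference similarity is partly degree-driven on scale-free
  graphs — which bounds masked-label recovery near AUC 0.7 for every
  learner tried. The directional claims (environment beats the
  no-environment baseline; fusing noisy views beats a single noisy
  view) reproduce clearly; the absolute bar of 0.80 in the acceptance
  suite does not, and is intentionally left failing rather than tuned
  to pass. See the test suite for the exact protocol.
* The CNN is intentionally minimal and trained on raw images; no
  augmentation, no hyperparameter search.
* Identifier mapping between proteins and genes is the caller's
  responsibility; networks are harmonized purely by identifier string.
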
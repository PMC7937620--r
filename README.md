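# netimage

Disease-gene prioritization from biological networks by turning each gene
into a small **image-like matrix** and classifying those images.

Candidate disease genes are usually scattered through large
protein–protein interaction (PPI), pathway, co-expression or
co-methylation networks. Two properties of such networks frustrate
straightforward graph learning: genes are **multifunctional** (one gene
may belong to several disease classes) and the networks are
**scale-free** (hubs see thousands of neighbours, leaves a handful), so
"take the graph neighbours" gives every gene a different amount of
information. `netimage` implements a representation that gives every
gene the *same* amount: a fixed `m × m` matrix combining local topology
with the disease-class environment of the gene's most similar peers.

## The representation

For a network with weighted adjacency `A` (genes as rows):

1. **Similarity** between genes *i* and *j* is the reciprocal of the sum
   of squared differences of their adjacency rows,
   `S_ij = 1 / Σ_k (a_ik − a_jk)²` — genes that influence the rest of
   the network identically are maximally similar.
2. **Leaf order.** Average-linkage agglomerative clustering on the
   consistent distance `1/S` yields a dendrogram; its left-to-right leaf
   sequence places similar genes next to each other.
3. **Receptive field.** For a centre gene, a window of radius `k` on the
   leaf sequence is the candidate pool; the `m − 1` candidates with the
   largest total similarity to the centre become its neighbourhood.
4. **Sub-adjacency `A_v`.** The `m × m` adjacency of the node-induced
   sub-network (centre first, neighbours in leaf order).
5. **Environment `C_v`.** A diagonal matrix holding each neighbour's
   disease-class value `c = t/4`, where `t` resolves the neighbour's
   (possibly multi-tag) class set against the centre's tag by centroid
   linkage between class centroids; unannotated neighbours contribute 0.
6. **Image.** `E_v = A_v + C_v` is the single-channel input to a small
   CNN; flattened to an `m²`-vector it feeds five classical learners
   (Gaussian/polynomial SVM, decision tree, extra-trees, naive Bayes).

Multiple network views of the same gene universe are fused by fixing the
neighbourhood on a reference view, min–max scaling each weighted view,
and averaging the per-view images elementwise. A no-environment baseline
(consecutive leaf successors, `E = A`) is included for ablation.

Because no public release of the curated input networks ships with the
package, a **synthetic generator** (degree-corrected planted partition
with power-law expected degrees, partial multi-tag annotation, and
correlated noisy views) stands in for them, so the entire pipeline is
testable end to end.

## Worked example

```r
library(netimage)
world <- generate_synthetic(synthetic_config(n = 400, K = 6, seed = 42))
ppi <- world$networks[[1]]
ann <- world$annotation
ppi
#> gene_network 'view1': 400 genes, 2981 edges (weighted)
ann
#> disease_annotation: 120 annotated genes, 6 classes, target 'class1' (22 multi-tag)

# one gene's image: sub-adjacency plus environmental diagonal
sim <- compute_similarity(ppi); ord <- leaf_order(sim)
img <- represent_vertex(ppi, ann, ord, sim, "g0007", k = 39, m = 5)
round(img$E, 2)
#>       g0007 g0326 g0073 g0358 g0029
#> g0007     0  0.00   0.0  0.00     0
#> g0326     0  0.00   0.8  0.45     0
#> g0073     0  0.80   0.5  0.00     0
#> g0358     0  0.45   0.0  0.00     0
#> g0029     0  0.00   0.0  0.00     0
```

The off-diagonal entries are edge weights among the selected
neighbourhood (here `g0326–g0073` with weight 0.8); the diagonal entry
0.5 is the class value of neighbour `g0073` (class 2, so `2/4`); zero
diagonal entries are unannotated neighbours.

```r
# balanced classification of the target class with masked evaluation
res <- run_experiment(ppi, ann, kind = "cnn", m = 13, k = 39, seed = 42)
res$report
#> evaluation_report: n=8  acc=0.7500  prec=0.7500  rec=0.7500  f1=0.7500  auc=0.6875  thr=0.4625
```

`run_experiment()` selects all target-class genes as positives, samples
an equal number of other-class genes as negatives, holds out a
stratified 20 %, **masks the held-out genes' tags during
representation** (so the representation cannot peek at the labels it is
asked to predict), trains the classifier and evaluates on the held-out
genes: confusion matrix, accuracy/precision/recall/F1, ROC, AUC and the
least-error threshold.

## Package layout

- `R/io.R`, `R/network.R` — edge-list / annotation I/O, gene-universe
  harmonization across views.
- `R/representation.R` — similarity, leaf order, receptive fields,
  `E = A + C` images, baseline, fusion.
- `R/classifiers.R`, `R/cnn.R` — the six learners (self-contained,
  including an SMO kernel SVM and a gradient-checked CNN).
- `R/evaluation.R` — ROC/AUC, confusion matrices, best threshold,
  report serialization.
- `R/synthetic.R` — the scale-free planted-partition generator.
- `vignettes/netimage-methods.Rmd` — model, assumptions, parameter
  choices, limitations.
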
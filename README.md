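# morphodesc

Unsupervised per-cell morphology descriptors for segmented 3D electron
microscopy volumes.

## What problem this solves, and for whom

Whole-specimen volume EM yields a raw intensity grid plus cell and nucleus
segmentation masks for thousands of cells — and no per-cell labels. For
anyone who wants to ask "which cells look alike?" at body scale (cell-type
discovery, tissue delineation, left–right partner matching, linking
morphology to gene expression), `morphodesc` learns a 480-dimensional
descriptor per cell without any annotation:

* six small neural encoders — point-cloud **shape**, low-resolution
  **coarse texture** and high-resolution **fine texture**, for the cell
  and for its nucleus — each emit 80 features;
* shape encoders are dynamic-graph convolutional networks over point
  clouds (1024 points + normals sampled from watertight membrane meshes),
  trained purely contrastively (NT-Xent) on mesh-deformation views
  (biharmonic / as-rigid-as-possible handle displacements plus rigid
  jitter);
* texture encoders are 3D U-Net-style convolutional encoders with masked
  global average pooling, trained with NT-Xent + an autoencoding
  reconstruction loss + an L2 bottleneck penalty on flip/rotation/elastic
  views;
* the six embeddings are concatenated in a fixed order into the per-cell
  descriptor, optionally extended with the mean descriptor of a cell's
  contact neighbourhood (region-adjacency-graph context features).

For a batch of `B` cells with two augmented views each, the contrastive
loss over cosine similarities `s` at temperature `tau` is

```
L = mean_i [ -log( exp(s(i, p(i))/tau) / sum_{j != i} exp(s(i, j)/tau) ) ]
```

with `p(i)` the other view of cell `i`.

The package also implements the evaluation and exploration protocol around
the descriptors: stratified cross-validated morphotype classification, the
bilateral symmetric-partner rank metric, Leiden/CPM clustering on a fuzzy
k-NN graph, gene and feature specificity statistics `C = 2AB/(A+B)`, and
representative/extreme cell selection — plus a synthetic phantom-volume
generator (mirrored cell pairs, one nucleus per cell, shape/texture
classes, contact structure) so the whole pipeline runs and is testable on
a desk CPU without any external data.

## Worked example

```r
library(morphodesc)

# a bilaterally symmetric phantom: 30 mirrored cell pairs,
# 3 shape x 2 texture classes, one nucleus per cell
res <- run_phantom_study(seed = 1, n_cell_pairs = 30, verbose = TRUE)

glance(res$probe)           # linear probe on the trained descriptors
glance(res$probe_random)    # same probe on random-init encoders
glance(res$bilateral)       # mirrored-partner median rank
```

With seed 1 this prints (about ten minutes on one CPU):

```
# probe on trained descriptors
  mean_accuracy sd_accuracy n_folds n_classes
1         0.933       0.109       5         6

# probe on random-init descriptors
  mean_accuracy sd_accuracy n_folds n_classes
1         0.844       0.158       5         6

# bilateral partner ranking
  median_rank n_cells n_skipped
1           1      56         0
```

Reading: a ridge logistic probe under stratified 5-fold cross-validation
recovers the six phantom classes from the trained descriptors with ~93%
accuracy versus ~84% for untrained encoders of the same architecture, and
the mirrored partner of a cell is typically the single nearest cell in
descriptor space (median rank 1 of 55 possible; 4 of 60 cells were
excluded for retaining no fine-texture patch and are listed in the
feature table's exclusion attribute).

Clustering and marker screening work on any feature table:

```r
feats <- standardize_features(res$features)
cl <- cluster_cells(feats, n_neighbours = 20, resolution = 0.004, seed = 1)
expr <- make_expression_table(res$phantom$truth, seed = 1)
spec <- gene_specificity(expr, cl)
plot_specificity_dots(select_specific(spec, threshold = 0.15))
```

A thin command-line front end (`exec/morphodesc`) exposes the stages as
subcommands (`synth`, `extract`, `train-shape`, `train-texture`, `embed`,
`context`, `classify`, `bilateral`, `cluster`, `specificity`,
`representatives`, `extremes`); volumes travel as plain uncompressed
Zarr v2 stores, meshes as PLY, tables as TSV.

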
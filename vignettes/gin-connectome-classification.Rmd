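---
title: "Classifying functional connectomes with an edge-weighted GIN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional connectomes with an edge-weighted GIN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingin)
```

## The problem

Resting-state fMRI yields, for every subject, a mean BOLD time series per
region of interest (ROI) of a cortical parcellation. The Pearson
correlations between all ROI pairs — the functional connectome — carry
information about clinical status: group differences in functional
connectivity have been reported repeatedly for neurodevelopmental
conditions such as autism spectrum disorder. braingin treats diagnosis as a
*graph classification* problem: each subject's connectome is one weighted
graph, and a Graph Isomorphism Network (GIN) learns to separate the two
diagnostic groups while exposing which ROIs its decision attends to.

## From time series to graphs

`compute_fc()` correlates every pair of ROI time series and applies the
Fisher z transform, `z = arctanh(r)`, which variance-stabilizes
correlations. The diagonal is a self-correlation, never transformed, and
fixed at zero. Because synthetic fixtures can legitimately contain exactly
collinear signals (`|r| = 1`, infinite z), correlations are clipped to
`1 - 1e-7` in magnitude before the transform; the clip is a flag
(`clip = FALSE` turns a perfect correlation into an error instead).

`build_graph()` sparsifies the connectome by edge density: of the
`N(N-1)/2` candidate connections, the strongest `M%` are retained
(`round()` half-up; ties at the cutoff are broken by descending ranking
key, then ascending node pair, so graphs are bit-reproducible). Three
edge-weight conventions are supported, because a correlation network has no
unique "edge strength":

* **abs** (default): rank by `|z|`, keep `|z|` — magnitude as strength;
* **positive_only**: discard anticorrelations, keep positive `z`;
* **signed**: rank by `|z|`, keep the signed value.

For the signed convention the ranking key is deliberately the *magnitude*:
ranking by the signed value itself would silently discard every strong
negative connection, defeating the purpose of keeping signs. Node features
are one-hot ROI identities — the graph carries connectivity in its edge
weights, and the features tell the network *which* region each node is, not
what its signal looked like.

## The classifier

Each of the `L = 4` GIN layers updates node `v`'s representation as

$$h_v^{(k)} = \mathrm{MLP}^{(k)}\!\Big((1+\epsilon^{(k)})\,h_v^{(k-1)}
  + \sum_{u \in N(v)} w_{uv}\, h_u^{(k-1)}\Big),$$

an injective sum aggregation (the discrete analogue of the
Weisfeiler–Lehman test) with the neighbour messages scaled by the retained
connectivity weights $w_{uv}$. Each undirected edge contributes in both
directions; an isolated node keeps only its scaled self term. The MLP has
two linear layers with batch normalization between them and ReLU
activations (the GIN convention; batch norm can be disabled). `epsilon` is
either frozen at zero (GIN-0, the default) or one learnable scalar per
layer initialized at 0.1.

**Pooling.** After every layer, gated attention pooling collapses node
embeddings to a graph embedding: a learned linear gate scores each node,
scores are softmax-normalized *across the nodes of the graph*,
independently per embedding dimension, and the graph embedding is the
gate-weighted sum

$$g^{(k)} = \sum_{i=1}^{N} \mathrm{softmax}\big(f_{gate}(x_i^{(k)})\big)
  \cdot x_i^{(k)}.$$

The softmax axis matters: the gate map is vector-valued
($f_{gate}: \mathbb{R}^{d} \to \mathbb{R}^{d}$), so normalization runs over
nodes within each dimension and every gate column sums to one — these
post-softmax values are the node-importance scores reused for saliency. A
scalar-gate variant (one softmax weight per node) is available as a
sensitivity check (`gate_mode = "scalar"`).

**Readout.** Each layer's graph embedding passes through its own linear
classifier and the class scores are summed over layers, so shallow
(local) and deep (global) representations both contribute to the
prediction; concatenating embeddings into a single linear layer is offered
as an alternative (`readout = "concat"`). Dropout (rate 0.2) is applied to
the pooled embeddings before the readout at training time only.

Training minimizes mean cross-entropy with Adam (learning rate 0.005).
Prediction is the argmax of the logits, with ties broken toward the
control class.

## Cross-validation and metrics

`gin_cv()` runs stratified k-fold cross-validation (default 10 folds).
Stratification by diagnosis is a deliberate choice: at roughly 30 subjects
per test fold, unstratified folds of an imbalanced cohort would add
substantial variance to every metric. Five metrics are reported per fold
and as mean ± SD across folds: accuracy, precision, recall, specificity
and F1, all with the case group as the positive class. A metric whose
denominator is zero is reported as a flagged 0, never `NaN`. Graph
construction uses global constants only, and every learned quantity
derives from the fold's training indices, so no information leaks from
test subjects.

## Salient ROIs

For each fold, the final trained model is applied once, in inference mode,
to that fold's *training* subjects, separated by diagnostic group. The
vector-valued gate of each layer is reduced to one score per node by
averaging over embedding dimensions (the mapping from a d-dimensional gate
to a single ranking score is not canonical; the mean is the simplest
symmetric choice), then averaged over the subjects of the group. Per
(fold, layer, group) the top quarter of ROIs by score (`q = ceiling(N/4)`,
i.e. 50 of 200) are marked, and an ROI enters the consolidated salient set
of a (layer, group) only if it was marked in *strictly more than* half of
the folds — an ROI selected in exactly 5 of 10 folds is excluded. Under a
fold-independent null this inclusion has probability
`P(Bin(10, 0.25) >= 6) ≈ 0.02` per ROI, which is the reference the null
tests compare against. `network_proportions()` summarizes each salient set
as its composition across the seven canonical functional networks (visual,
somatomotor, dorsal/ventral attention, limbic, frontoparietal control,
default mode).

## The synthetic cohort generator

`simulate_cohort()` draws each subject's `T x N` time-series matrix from a
zero-mean multivariate normal. The control correlation matrix has seven
contiguous latent blocks — a cartoon of the seven functional networks —
with within-block correlation `r0 = 0.2` and independent blocks. Case
subjects differ only on a planted subnetwork: all pairwise correlations
among `planted_rois` (default the first 20 ROIs) are raised by
`delta = 0.25`. Both targets are checked for positive definiteness at
construction. The default cohort shape (150 + 150 subjects, 200 ROIs,
T = 200) mirrors a typical multi-site resting-state study of roughly 300
subjects on a 200-parcel cortical atlas; `delta = 0.25` is a strong but
not degenerate effect — roughly 3–4 standard errors per planted edge at
T = 200 — so recovering it demonstrates the full pipeline, while
`delta = 0` provides the matched negative control. `toy_parcellation()`
labels the blocks with the seven network names so saliency summaries can
be exercised end to end; it is synthetic and anatomically meaningless.

What the generator deliberately does *not* emulate: hemodynamic response
and autocorrelated BOLD noise (samples are temporally independent), site
and scanner effects, head motion, negative baseline correlations, and
heterogeneous effect sizes across subjects. Passing the planted-recovery
tests therefore shows the pipeline is *correct and sensitive under its own
model*, not that comparable accuracy is attainable on clinical data —
real-data performance is bounded by exactly the nuisance structure the
generator omits.

## Numerical and implementation choices

* **Batching.** Minibatches (default 32 graphs) are assembled as one
  block-diagonal sparse adjacency, so a whole batch is a single set of
  sparse/dense matrix products; the hot loops (sparse aggregation, batch
  norm, softmax pooling) run in compiled code. Embeddings are stored
  feature-major internally; the user-facing API is node-major. Minibatch
  composition is drawn once per fit from the seeded shuffle and revisited
  each epoch.
* **Determinism.** Every stochastic step — initialization (Glorot
  uniform), shuffling, dropout — draws from a stream seeded by
  `control$seed`; cross-validation derives one disjoint stream per fold.
  Identical seeds reproduce metrics bit-for-bit on the same platform.
* **Softmax stability.** Gate scores are shifted by a per-dimension
  constant before exponentiation (any constant shift leaves the softmax
  exact); denominators are floored at `1e-300` as a last resort.
* **Batch norm** uses biased batch variance with running statistics
  (momentum 0.1) for inference; `1e-5` is added inside the square root.
* **Epoch budget.** Fixed epochs, no early stopping (early stopping would
  make the learned state depend on evaluation-order details and
  complicate reproducibility). The package default is 200 epochs; the
  bundled experiments use 50, where training on the synthetic cohorts has
  long converged.
* **Problem sizes in the bundled experiments.** The acceptance script and
  the heavy tests run the full study shape (300 subjects, 200 ROIs,
  10-fold CV, 50 epochs) with hidden width 16 — a deliberately compact
  width in line with GIN widths used on graphs of this size; the package
  default is 64. Unit tests use miniature cohorts (10–40 subjects, 10–20
  ROIs) where every property is checkable in seconds.
* **Checkpoints** are single-file RDS archives with a schema version;
  restoring one reproduces logits bit-exactly.

## Limitations

The model ingests a single connectivity matrix per subject: dynamic
(time-varying) connectivity, multi-modal node features and edge-level
saliency are out of scope. The attention scores rank nodes by their
contribution to the pooled representation; they are not statistical tests
of group difference, and the salient-set rule controls only frequency
across folds, not a false-discovery rate. In particular, cross-validation
folds share most of their training subjects and all of their graphs, so
attention rankings are correlated across folds: under a label permutation
the consolidated sets shrink markedly but remain larger than the
fold-*independent* binomial tail `N * P(Bin(K, q/N) > K/2)` would predict,
because graph structure alone (e.g. systematically distinctive
connectivity of some regions) stabilizes part of the ranking. Salient sets
should therefore be read against a permutation baseline computed on the
same cohort, not against that closed-form null. fMRI preprocessing (motion
correction, denoising, parcellation) is assumed done upstream.
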
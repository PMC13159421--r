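---
title: "Contrastive meta-learning for spatial transcriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive meta-learning for spatial transcriptomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatial transcriptomics assays measure a gene expression vector at each of
thousands of capture locations ("spots") together with the spot's position
in the tissue. The central analysis task is *spatial domain
identification*: partitioning the spots into contiguous regions of coherent
expression (cortical layers, tumour compartments, germinal centres).
Per-spot expression is high-dimensional, sparse, and noisy, so clustering
expression alone usually fragments tissue structure; the spatial
arrangement carries the missing information.

`spotmeta` learns a low-dimensional representation $h_v \in \mathbb{R}^{d_h}$
for every spot $v$ that fuses both signals, and applies it to four
downstream tasks: domain identification, gene expression imputation,
embedding export for trajectory inference, and LISI-based
batch-integration scoring.

## Model

**Spatial graph.** Spots become nodes of a k-nearest-neighbour graph built
from coordinates only: every spot selects its $\min(k, C-1)$ spatially
nearest spots (ties broken by lower index) and the edge set is the union
symmetrisation, giving a binary symmetric adjacency $A$ with zero
diagonal. The default $k = 6$ matches the hexagonal neighbourhood of
Visium arrays. We treat similarity as negative Euclidean distance; a raw
coordinate inner-product variant is available
(`similarity = "inner_product"`) but it favours spots far from the
coordinate origin and is not a proximity measure, so it is not the
default.

**Subgraph encoder.** Each spot is encoded from its *two-hop subgraph*:
the induced subgraph on $\{v\} \cup \{u : 1 \le d(v,u) \le 2\}$, with BFS
distance $d$. A graph convolutional network with Kipf-style symmetric
renormalisation $\hat{A} = \tilde{D}^{-1/2}(A_v + I)\tilde{D}^{-1/2}$
propagates features through the subgraph; the centre-node row of the final
layer is the spot embedding. The centre-row readout (rather than pooling)
guarantees locality: expression changes at spots more than two hops away
cannot affect $h_v$. Three-hop neighbourhoods are deliberately
unsupported — they add cost without improving the representation.

**Pseudo-labelling.** A variance-aware soft K-means on the expression
matrix assigns responsibilities
$p_{i,k} \propto \exp(-\tfrac12 \lVert x_i - \mu_k\rVert^2 / \sigma_k^2)$,
updates centroids by responsibility-weighted means, and hardens to
$y_i = \arg\max_k p_{i,k}$. $K = 10$ is used for all datasets. The
variance estimator
$\sigma_k^2 = \sum_i p_{i,k}\lVert x_i-\mu_k \rVert^2 / (g \sum_i p_{i,k})$
(floored at $10^{-6}$) is the isotropic completion of the assignment rule;
initialisation is k-means++ under the run seed and iteration stops when the
largest responsibility change falls below $10^{-5}$ (or 300 iterations).
With responsibilities hardened and variances frozen the procedure reduces
exactly to Lloyd's K-means, which the test suite exploits as an oracle.

**Episodic training.** Each episode samples $N$ pseudo-label classes, up
to $M$ support spots per class, and up to $Q$ query spots (disjoint from
the support). With class prototypes
$\hat{h}_i = \frac{1}{M}\sum_j h_i^j$, the support set contributes the
prototype contrastive loss

$$
L_{CT} = -\frac{1}{NM}\sum_{i=1}^{N}\sum_{j=1}^{M}
\log \frac{\exp(h_i^j \cdot \hat{h}_i / \tau)}
{\sum_{k \ne i} \exp(h_i^j \cdot \hat{h}_k / \tau)},
$$

and the query set the cross-entropy $L_{CE}$ of a prototype-similarity
softmax $p_i(j) = \mathrm{softmax}_j(h'_i \cdot \hat{h}_j / \tau)$ against
the one-hot pseudo-labels. One Adam step is taken per episode on
$L_T = \alpha L_{CT} + (1-\alpha) L_{CE}$. Embeddings enter both losses
un-normalised (dot products, no l2 normalisation). A sequential mode
(`sequential_updates = TRUE`) takes the two loss terms as two consecutive
steps instead of one joint step; the joint step is the default because the
combined objective is what $L_T$ defines.

## Design choices in the open parts

Several components are not pinned down by the loss definitions; the
package completes them as follows and treats each as a tunable.

**Per-gene standardisation (`scale_genes = TRUE`).** The encoder consumes
expression "after preprocessing". Raw counts-scale expression carries a
large shared baseline across genes, and because the symmetric-normalised
adjacency has degree-dependent row sums, that baseline is rescaled
slightly differently per spot — enough jitter to swamp modest between-domain
separation. Standardising each gene (centre, unit variance) before
pseudo-labelling and encoding removes the baseline and is the conventional
preparation for expression fed to graph encoders. Disable it if the input
is already standardised.

**Pseudo-label refresh (`refresh_pseudo_labels = TRUE`).** Initial
pseudo-labels come from expression alone, before any training. At
realistic noise levels expression-only K-means is a weak teacher, and
episodic training against a weak teacher can *degrade* the encoder below
its random initialisation — we measured exactly that on synthetic
benchmarks. Re-clustering the current embeddings at the end of each epoch
turns the procedure into cluster-aware self-training: the spatially
smoothed embeddings yield far cleaner labels, and the contrastive
objective then sharpens them. Refresh is therefore the default; set
`refresh_pseudo_labels = FALSE` for strictly fixed pseudo-labels.

**Stability of the contrastive objective.** $L_{CT}$ excludes the positive
class from its denominator. In the un-normalised embedding regime this
objective is unbounded below: uniformly scaling all embeddings up
increases $h \cdot \hat{h}_{pos} - \log\sum_{k\ne i}\exp(h \cdot \hat{h}_k)$
without limit, so sufficiently long or aggressive training drives
embedding norms to infinity and destroys the geometry K-means needs. The
loss implementation keeps the formula exact (the test suite asserts it
against direct evaluation); the *trainer* manages the instability through
a moderate learning rate (default `3e-4`), short episodic schedules, and
optional decoupled weight decay (`weight_decay`) and embedding-norm
regularisation (`embed_reg`), both off by default. Watch `l_ct` in the
training log: values running away towards $-10^3$ and beyond indicate the
runaway regime.

**Architecture.** Default: two GCN layers, hidden width 128,
$d_h = 64$, ELU between layers, linear output, Glorot-uniform
initialisation from the run seed. ELU is preferred over ReLU for centred
inputs: ReLU zeroes half of every random projection and measurably costs
embedding quality, while ELU stays near-identity on the positive side.
All of this is exposed in `run_config()`.

**Other defaults.** Temperature $\tau = 0.5$ (moderate values 0.5–1 work
best), $\alpha = 0.5$, 5-way 5-shot episodes with 15 queries, 30 episodes
per epoch for 10 epochs, Adam, 80/10/10 train/validation/test splits with
largest-remainder rounding.

## Downstream tasks

**Domain identification** runs Lloyd K-means (k-means++ seeding, best of
10 restarts) on the embedding matrix $H$, minimising
$L_{cluster} = \sum_i \lVert h_i - \mu_{z_i}\rVert^2$; the per-iteration
objective trace is returned and is non-increasing by construction. Set the
cluster count to the annotation count when ground truth exists.

**Imputation** is a post hoc linear map $\hat{X} = H W_X + b_X$ fitted by
closed-form ridge regression (default $\lambda = 10^{-3}$) — deterministic
and exactly testable, unlike a gradient-descent fit. An optional mask
argument excludes synthetically dropped-out entries from the fit so the
masked-recovery evaluation never trains on its own targets.

**LISI scoring** computes, per spot, the inverse Simpson index of label
proportions over a Gaussian-kernel neighbourhood whose bandwidth is tuned
by binary search to a target perplexity (default 30, the conventional
choice). Means over spots are normalised to $[0,1]$ by
$\mathrm{ncLISI} = (N_{ct} - \mathrm{cLISI})/(N_{ct}-1)$ and
$\mathrm{niLISI} = (\mathrm{iLISI}-1)/(N_{ds}-1)$. Batch correction itself
(e.g. Harmony) is out of scope; externally corrected embeddings can be
scored directly.

**Trajectory export** writes embeddings plus cluster labels as CSV for
external UMAP/PAGA tooling; no trajectory computation happens in-package.

## The synthetic-data generator

`generate_dataset()` emulates the input modality end to end: spots on a
near-square grid (or uniform at random), domains as horizontal bands of
equal height (or Voronoi cells of random seeds), a Gamma(4, 1.5) baseline
expression vector shared across domains, folded-normal domain deviations,
additive Gaussian noise clipped at zero, independent Bernoulli dropout,
and additive per-batch gene-wise shifts. Deviations are scaled so that the
*expected Euclidean separation between two domain mean vectors equals
`effect_size`* — so `effect_size = 3` at `noise_sd = 1` is a 3-sigma task
in which expression-only K-means recovers domains only partially
(ARI around 0.4–0.6) while spatially informed embeddings recover them
well (ARI above 0.9). The baseline is kept well above zero so clipping is
rare and the planted means remain the true means.

What the generator does *not* emulate: count distributions (no negative
binomial), cell-type mixtures within spots, histology, or spatially
correlated noise. Passing tests on these fixtures demonstrates that the
machinery recovers planted structure in the intended regime, not that it
matches any particular real-tissue benchmark.

## Evaluation

`clustering_metrics()` implements ARI (pair counting), NMI
(arithmetic-mean normalisation — the most common convention), ACC via an
optimal one-to-one Hungarian matching of clusters to classes, purity, and
homogeneity ($1 - H(\text{class}\mid\text{cluster})/H(\text{class})$,
natural logs, $0\log 0 = 0$). `imputation_metrics()` reports PCC, L1, and
RMSE over masked entries. `run_multi_seed()` repeats the whole pipeline
over seeds — re-split (80/10/10), re-initialise, retrain, re-evaluate —
and reports per-seed values with mean ± sd, the mean being the
dataset-level summary. `compare_paired_scores()` wraps the two-sided
Wilcoxon signed-rank test for paired per-dataset comparisons.

Problem sizes used by the test suite and the acceptance script: the
domain-recovery benchmark is 600 spots × 60 genes with 4 domains over 5
training runs; imputation uses 400 spots × 40 genes with 20% masking;
LISI uses a 400-spot two-batch fixture. These sizes keep every fixture
generable in code in seconds while leaving the statistical comparisons
(model vs raw K-means, model vs gene-mean baseline) clearly resolved.

## Numerical notes and limitations

* Soft assignments and all softmaxes are evaluated with log-sum-exp
  stabilisation; responsibilities never underflow to zero rows.
* Starved soft K-means clusters are re-seeded at the least-committed
  points; empty Lloyd clusters at the farthest points from their
  centroids. Distance ties break to the lower index everywhere, which
  makes lattice data deterministic.
* Query probabilities exactly at zero for the true class are clamped to
  $10^{-12}$ with a warning before the log.
* All randomness flows through explicit seeds; two runs with the same
  configuration are bitwise identical.
* The contrastive objective's unboundedness (above) is a property of the
  model class, not of this implementation; very long training schedules
  require the regularisation knobs.
* Batch-effect *removal* is not implemented — only its measurement.
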
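# spotmeta

Contrastive meta-learning for spatial transcriptomics spot embeddings.

Spatial transcriptomics assays measure a gene expression vector at each
capture spot together with the spot's tissue coordinates. The analysis
bottleneck is **spatial domain identification** — partitioning spots into
contiguous regions of coherent expression — because per-spot expression is
too noisy to cluster on its own. `spotmeta` learns, for every spot $v$, a
representation $h_v \in \mathbb{R}^{d_h}$ that fuses expression with
spatial context:

1. a k-nearest-neighbour graph over spot coordinates (binary symmetric
   adjacency $A$, default $k = 6$);
2. a graph convolutional encoder over each spot's **two-hop subgraph**
   ($N_v = \{u : 1 \le d(v,u) \le 2\}$, Kipf renormalisation
   $\tilde{D}^{-1/2}(A_v + I)\tilde{D}^{-1/2}$, centre-node readout);
3. **soft K-means pseudo-labels** on expression,
   $p_{i,k} \propto \exp(-\tfrac12 \lVert x_i - \mu_k \rVert^2 / \sigma_k^2)$,
   hardened to $y_i = \arg\max_k p_{i,k}$ ($K = 10$), refreshed from the
   embeddings each epoch;
4. **episodic training**: N-way M-shot support/query episodes, prototype
   contrastive loss
   $L_{CT} = -\frac{1}{NM}\sum_{i,j} \log
   \frac{\exp(h_i^j\cdot\hat h_i/\tau)}{\sum_{k\ne i}\exp(h_i^j\cdot\hat h_k/\tau)}$
   plus query cross-entropy $L_{CE}$, combined as
   $L_T = \alpha L_{CT} + (1-\alpha) L_{CE}$, one Adam step per episode.

The embeddings drive four downstream tasks: K-means domain identification
(objective $L_{cluster} = \sum_i \lVert h_i - \mu_{z_i} \rVert^2$), post
hoc linear gene-expression imputation ($\hat X = H W_X + b_X$, closed-form
ridge), embedding export for trajectory tools (UMAP/PAGA), and LISI-based
batch-integration scoring with the $[0,1]$ normalisations
$\mathrm{ncLISI} = (N_{ct}-\mathrm{cLISI})/(N_{ct}-1)$,
$\mathrm{niLISI} = (\mathrm{iLISI}-1)/(N_{ds}-1)$.

A synthetic-data generator with planted spatial domains, the full metric
suite (ARI, NMI, Hungarian-matched ACC, purity, homogeneity; PCC/L1/RMSE),
and a multi-seed 80/10/10 evaluation harness make every stage testable
without external data.

## Worked example

```r
library(spotmeta)

# a 400-spot tissue with 3 planted horizontal-band domains
d <- generate_dataset(synthetic_spec(
  n_spots = 400, n_genes = 40, n_domains = 3,
  effect_size = 3, noise_sd = 1, seed = 42
))
d
#> <spot_dataset> 400 spots x 40 genes, 2-D coordinates
#>   batches: 1
#>   true domains: 3

fit <- train_encoder(d, config = run_config(n_epochs = 8L, seed = 42))
fit
#> <spotmeta_fit> 400 spots embedded in 64 dimensions after 240 episodes
#>   final losses (last 10 episodes): L_CT -49.2381, L_CE 8.7998, L_T -20.2191

dom <- identify_domains(fit$embeddings, 3, seed = 42)
clustering_metrics(dom$assignments, d$true_labels)
#>         ari         nmi         acc      purity homogeneity
#>   0.9569961   0.9442840   0.9850000   0.9850000   0.9449807
```

An ARI of 0.96 against the planted domains, versus roughly 0.4–0.6 for
K-means on the raw expression of the same fixture: the spatial graph is
doing the work. `autoplot(fit)` draws the per-episode loss curves,
`plot_domains(dom, d$coordinates)` the spatial domain map, and
`tidy()`/`glance()` return tibbles for fits, domain results, and
multi-seed reports.

Imputation and integration scoring follow the same pattern:

```r
head_fit <- fit_imputation_head(fit$embeddings, d$expression)
x_hat    <- impute_expression(fit$embeddings, head_fit)
lisi     <- compute_lisi(fit$embeddings, d$true_labels, perplexity = 30)
```

A thin command-line wrapper lives at `inst/cli/spotmeta.R`
(`run`, `simulate`, and `evaluate` subcommands over CSV/MTX inputs and a
YAML config).

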
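# milocfuse

Multi-label prediction of **miRNA subcellular localisation** across seven
compartments (cytoplasm, exosome, nucleolus, nucleus, extracellular vesicle,
microvesicle, mitochondrion) by fusing five feature families through a gated
multi-head cross-attention head.

Mature miRNAs act where they reside — cytoplasmic silencing, nuclear
regulation, exosomal cell-to-cell signalling — and one miRNA can occupy
several compartments at once. `milocfuse` treats localisation as a
multi-label classification problem over miRNA-indexed evidence:

* **Sequence**: Smith–Waterman local alignment, self-normalised to
  `SW(i,j) = sp(i,j) / sqrt(sp(i,i) · sp(j,j))`;
* **Disease**: MeSH-style DAG semantic similarity (ancestor contributions
  `Δ^k`, Δ = 0.5) averaged over annotation sets, patched by a Gaussian
  interaction-profile kernel `GIP(i,j) = exp(−γ‖y_i − y_j‖²)` where the
  functional similarity is zero;
* **Disease / drug / mRNA networks**: node2vec embeddings of each bipartite
  association network, refined by 3-layer hypergraph convolution
  `H^{l+1} = σ(D_v^{-1/2} H W B^{-1} Hᵀ D_v^{-1/2} · H^l W^l)` over
  similarity- and association-derived hyperedges;
* **mRNA localisation propagation**: the fraction of a miRNA's target mRNAs
  annotated to each compartment.

A softmax modality gate selects informative branches, multi-head
cross-attention (gated selection as query, full concatenation as key/value)
mixes them, and a residual MLP outputs 7 sigmoid probabilities trained with
multi-label binary cross-entropy (Adam, batch 64, ≤100 epochs, early
stopping). Evaluation is k-fold cross-validation with per-compartment
AUC / AUPR on pooled out-of-fold predictions.

Because the real multi-database benchmark cannot be bundled, the package
ships a synthetic-data generator with a *planted* localisation signal
(latent communities, community-enriched networks, labels inherited from the
thresholded mRNA propagation), so every stage — and the whole pipeline — is
testable offline.

## A worked example

```r
library(milocfuse)

cfg <- synth_config(n_mirna = 100L, n_disease = 30L, n_drug = 10L, n_mrna = 70L,
                    density_disease = 0.1, density_drug = 0.12, density_mrna = 0.1,
                    seed = 7L)
bundle <- generate_dataset(cfg)
#> <milocfuse_bundle> 100 miRNAs, 30 diseases, 10 drugs, 70 mRNAs (seed 7)

fx <- assemble_features(
  bundle, n2v = node2vec_params(num_walks = 5L, walk_length = 40L,
                                window = 5L, epochs = 3L), seed = 7L)
input <- model_input(fx$features, fx$hypergraphs, fx$labels)
cv <- cross_validate(input, model_config(seed = 7L), k = 3L)
cv
#> <milocfuse_cv> 3-fold; mean AUC 0.7853, mean AUPR 0.6068
#> # A tibble: 7 × 3
#>   compartment             auc  aupr
#>   <chr>                 <dbl> <dbl>
#> 1 cytoplasm             0.853 0.729
#> 2 exosome               0.838 0.670
#> 3 nucleolus             0.792 0.610
#> 4 nucleus               0.735 0.534
#> 5 extracellular_vesicle 0.730 0.613
#> 6 microvesicle          0.849 0.599
#> 7 mitochondrion         0.701 0.493
```

The per-compartment rows are pooled out-of-fold metrics: the AUC column is
the probability that a miRNA annotated to that compartment outranks one
that is not; AUPR is the average precision, which is sensitive to the
compartment's prevalence. `tidy(cv)`, `glance(cv)` and `autoplot(cv)` give
tibble and ggplot views; `tidy(fit)` / `autoplot(fit)` show a trained
model's loss history. With the stronger default generator signal
(n = 300, β = 0.8) and 5-fold CV the pooled mean AUC is ≈ 0.82 — most of
the ≈ 0.87 ceiling the generator's label noise allows (20% of rows carry
random labels and 5% of bits are flipped; see the methods vignette).

`run_pipeline()` (or the `inst/cli/milocfuse` script) orchestrates the
staged workflow — similarities → embeddings → hypergraph operators →
propagation → training/CV — with checksum-keyed per-stage caching, a
JSON-lines log and a reproduction manifest. `run_ablation()` and
`sweep_hg_layers()` drive the ablation and layer-sweep experiments.

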
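# Memoised cross-validation experiments shared by the acceptance tests, so
# that e.g. the full-model runs reused by the signal-monotonicity and
# ablation checks are trained once per test session.
#
# Problem sizes: the headline planted-signal run uses the generator defaults
# (n = 300); the multi-seed sweeps use n = 100 three-fold runs, which carry
# the same planted structure at a fraction of the cost.

sweep_synth_config <- function(beta, seed) {
  synth_config(n_mirna = 100L, n_disease = 30L, n_drug = 10L, n_mrna = 70L,
               density_disease = 0.1, density_drug = 0.12, density_mrna = 0.1,
               signal_strength = beta, seed = seed)
}

# full feature assembly + CV for one (beta, seed, ablation) cell
sweep_cv <- function(beta, seed, ablation = character(), k = 3L) {
  key <- paste0("sweep_", beta, "_", seed, "_", paste(ablation, collapse = "."))
  memo(key, function() {
    bundle <- generate_dataset(sweep_synth_config(beta, seed))
    fx <- suppressMessages(assemble_features(bundle, n2v = test_n2v(),
                                             seed = seed))
    input <- model_input(fx$features, fx$hypergraphs, fx$labels,
                         ablation = ablation)
    config <- model_config(seed = seed, ablation = ablation)
    cross_validate(input, config, k = k)
  })
}

headline_cv <- function() {
  memo("headline_cv", function() {
    bundle <- generate_dataset(synth_config(seed = 0L))
    fx <- suppressMessages(assemble_features(bundle, n2v = test_n2v(),
                                             seed = 0L))
    input <- model_input(fx$features, fx$hypergraphs, fx$labels)
    cross_validate(input, model_config(seed = 0L), k = 5L)
  })
}
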
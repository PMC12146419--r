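# Shared fixtures, built in code. Expensive objects are memoised in an
# environment so the whole test run constructs each one once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# light node2vec settings used in experiment fixtures (documented problem
# sizes; embeddings only need to carry community structure here)
test_n2v <- function() {
  node2vec_params(num_walks = 5L, walk_length = 40L, window = 5L, epochs = 3L)
}

# small bundle for unit tests of io / features / model wiring
tiny_bundle <- function(seed = 11L) {
  memo(paste0("tiny_bundle_", seed), function() {
    generate_dataset(synth_config(n_mirna = 40L, n_disease = 15L, n_drug = 6L,
                                  n_mrna = 30L, density_disease = 0.12,
                                  density_drug = 0.15, density_mrna = 0.12,
                                  seed = seed))
  })
}

tiny_features <- function(seed = 11L) {
  memo(paste0("tiny_features_", seed), function() {
    b <- tiny_bundle(seed)
    suppressMessages(assemble_features(
      b, n2v = node2vec_params(dim = 16L, num_walks = 4L, walk_length = 20L,
                               window = 4L, epochs = 2L),
      seed = seed))
  })
}

# a small but non-trivial model input + config for head/training tests
tiny_model_setup <- function(seed = 11L) {
  memo(paste0("tiny_model_", seed), function() {
    fx <- tiny_features(seed)
    b <- tiny_bundle(seed)
    input <- model_input(fx$features, fx$hypergraphs, b$labels)
    config <- model_config(d_model = 16L, n_heads = 2L, dropout = 0.2,
                           epochs = 15L, patience = 10L, hg_layers = 2L,
                           batch_size = 16L, seed = seed)
    list(input = input, config = config)
  })
}

# random token lists for attention/gate unit tests
random_tokens <- function(nb, B, d, seed = 1) {
  set.seed(seed)
  lapply(seq_len(B), function(b) matrix(rnorm(nb * d), nb, d))
}

random_att_params <- function(d, seed = 1) {
  set.seed(seed)
  list(wq = matrix(rnorm(d * d, sd = 0.3), d, d), bq = rnorm(d, sd = 0.1),
       wk = matrix(rnorm(d * d, sd = 0.3), d, d), bk = rnorm(d, sd = 0.1),
       wv = matrix(rnorm(d * d, sd = 0.3), d, d), bv = rnorm(d, sd = 0.1),
       wo = matrix(rnorm(d * d, sd = 0.3), d, d), bo = rnorm(d, sd = 0.1))
}
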
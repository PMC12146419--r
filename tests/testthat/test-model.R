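test_that("modality gate weights sum to one and rescale tokens", {
  tokens <- random_tokens(nb = 6, B = 3, d = 8, seed = 2)
  w <- matrix(rnorm(24 * 3, sd = 0.3), 24, 3)
  g <- modality_gate(tokens, w, rnorm(3))
  expect_equal(unname(rowSums(g$weights)), rep(1, 6), tolerance = 1e-12)
  expect_equal(g$selected[[2]], g$weights[, 2] * tokens[[2]])
  # equal logits (zero map) -> uniform weights
  gu <- modality_gate(tokens, matrix(0, 24, 3), 0)
  expect_equal(unname(gu$weights), matrix(1 / 3, 6, 3), tolerance = 1e-12)
  # an overwhelming logit takes all the weight in the limit
  gb <- modality_gate(tokens, matrix(0, 24, 3), c(0, 100, 0))
  expect_equal(unname(gb$weights[, 2]), rep(1, 6), tolerance = 1e-10)
  expect_error(modality_gate(list(), w), "no branch")
})

test_that("multi-head cross-attention matches the loop oracle", {
  for (case in list(list(nb = 2, B = 3, heads = 2, d = 8),
                    list(nb = 5, B = 4, heads = 4, d = 16),
                    list(nb = 1, B = 2, heads = 1, d = 4))) {
    q <- random_tokens(case$nb, case$B, case$d, seed = case$nb)
    k <- random_tokens(case$nb, case$B, case$d, seed = case$nb + 50)
    att <- random_att_params(case$d, seed = case$nb + 100)
    got <- multi_head_cross_attention(q, k, k, att, case$heads)
    want <- attention_oracle(q, k, k, att, case$heads)
    for (b in seq_len(case$B)) {
      expect_equal(got$output[[b]], want[[b]], tolerance = 1e-6)
    }
    # attention rows sum to one per head
    for (h in seq_len(case$heads)) {
      for (b in seq_len(case$B)) {
        al <- got$cache$alpha[[h]][[b]]
        expect_equal(unname(rowSums(al)), rep(1, case$nb), tolerance = 1e-12)
      }
    }
  }
  expect_error(multi_head_cross_attention(random_tokens(2, 2, 6),
                                          random_tokens(2, 2, 6),
                                          random_tokens(2, 2, 6),
                                          random_att_params(6), 4),
               "divisible")
})

test_that("a single token receives attention weight exactly one", {
  q <- random_tokens(3, 1, 8, seed = 9)
  att <- random_att_params(8, seed = 9)
  got <- multi_head_cross_attention(q, q, q, att, 2)
  for (h in 1:2) {
    expect_equal(unname(got$cache$alpha[[h]][[1]]), matrix(1, 3, 1))
  }
})

test_that("binary cross-entropy matches hand-computed values", {
  expect_equal(bce_loss(matrix(1), matrix(0.5)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(matrix(c(1, 0), 1), matrix(c(0.9, 0.2), 1)),
               -(log(0.9) + log(0.8)), tolerance = 1e-12)
  # the per-sample average sums over compartments; "elements" divides by C too
  y <- matrix(c(1, 0, 1, 1), 2)
  p <- matrix(c(0.8, 0.3, 0.6, 0.9), 2)
  expect_equal(bce_loss(y, p), 2 * bce_loss(y, p, average = "elements"),
               tolerance = 1e-12)
  # perfect confident predictions approach zero loss
  expect_lt(bce_loss(y, ifelse(y == 1, 1 - 1e-9, 1e-9)), 1e-5)
  # the labels themselves (clamped) minimise the loss
  set.seed(6)
  for (r in 1:20) {
    yy <- matrix(rbinom(12, 1, 0.5), 3)
    pp <- matrix(runif(12), 3)
    expect_lte(bce_loss(yy, yy), bce_loss(yy, pp))
  }
  expect_error(bce_loss(matrix(1), matrix(0.5, 2, 1)), "shape")
})

test_that("analytic gradients match finite differences across the whole head", {
  setup <- tiny_model_setup()
  cfg <- setup$config
  cfg$dropout <- 0 # deterministic forward for finite differences
  inp <- setup$input
  set.seed(31)
  params <- milocfuse:::init_params(inp, cfg)
  idx <- c(2, 9, 17, 30)
  y <- inp$y[idx, , drop = FALSE]
  fw <- function(p) {
    bce_loss(y, milocfuse:::forward_localizer(p, inp, idx, cfg)$probs,
             cfg$loss_average)
  }
  cache <- milocfuse:::forward_localizer(params, inp, idx, cfg)
  grads <- milocfuse:::backward_localizer(params, cache, y, cfg)
  bump <- function(pp, path, ii, d) {
    if (length(path) == 1) {
      pp[[path[[1]]]][ii] <- pp[[path[[1]]]][ii] + d
    } else {
      pp[[path[[1]]]] <- bump(pp[[path[[1]]]], path[-1], ii, d)
    }
    pp
  }
  paths <- list(list("mlp", "wout"), list("mlp", "w1"), list("mlp", "b2"),
                list("ln", "gamma"), list("ln", "beta"),
                list("att", "wq"), list("att", "wk"), list("att", "wv"),
                list("att", "wo"), list("gate", "w"),
                list("proj", "seq", "w"), list("proj", "mrna_loc", "b"),
                list("hg", "disease", 1), list("hg", "mrna_net", 2))
  for (path in paths) {
    p <- params; g <- grads
    for (k in path) { p <- p[[k]]; g <- g[[k]] }
    for (ii in sample(length(p), 2)) {
      num <- (fw(bump(params, path, ii, 1e-6)) -
                fw(bump(params, path, ii, -1e-6))) / 2e-6
      expect_equal(g[ii], num, tolerance = 1e-4)
    }
  }
})

test_that("inference probabilities are in (0,1), deterministic, and row-local", {
  setup <- tiny_model_setup()
  fit <- train_localizer(setup$input, setup$config)
  p1 <- predict_proba(fit, setup$input)
  p2 <- predict_proba(fit, setup$input)
  expect_identical(p1$probs, p2$probs) # dropout off at inference
  expect_true(all(p1$probs > 0 & p1$probs < 1))
  expect_equal(dim(p1$probs), c(40, 7))
  # forward pass has no cross-sample mixing: a row's prediction does not
  # depend on which other rows are in the batch
  sub <- predict_proba(fit, setup$input, idx = c(3, 12, 25))
  expect_equal(sub$probs, p1$probs[c(3, 12, 25), ], tolerance = 1e-12)
})

test_that("training is reproducible and decreases the training loss", {
  setup <- tiny_model_setup()
  f1 <- train_localizer(setup$input, setup$config)
  f2 <- train_localizer(setup$input, setup$config)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  h <- f1$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_lte(nrow(h), setup$config$epochs)
})

test_that("a constant-label dataset converges to the class prevalence", {
  set.seed(77)
  ids <- sprintf("m%02d", 1:30)
  x <- feature_matrix(ids, matrix(rnorm(30 * 5), 30, 5), "mrna_loc")
  prev <- c(1, 0, 0, 1, 0, 0, 0)
  y <- localization_matrix(ids, matrix(rep(prev, each = 30), 30, 7))
  inp <- model_input(list(mrna_loc = x), labels = y)
  cfg <- model_config(d_model = 8L, n_heads = 2L, dropout = 0, epochs = 200L,
                      batch_size = 10L, val_fraction = 0, seed = 3L)
  fit <- train_localizer(inp, cfg)
  probs <- predict_proba(fit, inp)$probs
  expect_equal(unname(colMeans(probs)), prev, tolerance = 0.1)
})

test_that("ablation flags rewire the model as documented", {
  setup <- tiny_model_setup()
  fx <- tiny_features()
  b <- tiny_bundle()
  # branch removal drops the branch from the input
  inp <- model_input(fx$features, fx$hypergraphs, b$labels,
                     ablation = c("no_drug", "no_loc"))
  expect_setequal(names(inp$branches), c("seq", "disease", "mrna_net"))
  # no_hypergraph detaches the operators so raw embeddings feed forward
  inp2 <- model_input(fx$features, fx$hypergraphs, b$labels,
                      ablation = "no_hypergraph")
  expect_true(all(vapply(inp2$branches, function(b) is.null(b$a_hat),
                         logical(1))))
  # no_cross_attention mean-pools the projected tokens: with a single branch
  # the pooled representation is that branch's projection
  cfg <- setup$config
  cfg$ablation <- "no_cross_attention"
  inp3 <- model_input(fx$features["mrna_loc"], list(), b$labels)
  set.seed(5)
  params <- milocfuse:::init_params(inp3, cfg)
  cache <- milocfuse:::forward_localizer(params, inp3, 1:5, cfg)
  expect_identical(cache$fpool, cache$h[["mrna_loc"]])
  expect_null(cache$gate)
})

test_that("layer-norm rows are standardised before the affine map", {
  u <- matrix(rnorm(40), 8, 5)
  ln <- milocfuse:::layer_norm_rows(u, gamma = rep(1, 5), beta = rep(0, 5))
  expect_equal(unname(rowMeans(ln$out)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(ln$out, 1, function(r) mean(r^2))), rep(1, 8),
               tolerance = 1e-3) # eps-regularised variance
})

test_that("the forward pass stays finite across random seeds", {
  setup <- tiny_model_setup()
  cfg <- setup$config
  for (s in 1:20) {
    set.seed(s)
    params <- milocfuse:::init_params(setup$input, cfg)
    cache <- milocfuse:::forward_localizer(params, setup$input, 1:10, cfg)
    expect_true(all(is.finite(cache$probs)))
  }
})
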
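test_that("k-fold assignment is balanced, exhaustive and seeded", {
  f <- kfold_indices(10, 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 1))
  f2 <- kfold_indices(25, 10, seed = 2)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_identical(kfold_indices(25, 10, seed = 3), kfold_indices(25, 10, seed = 3))
  expect_error(kfold_indices(5, 10), "n < k")
})

test_that("ROC AUC matches brute-force pair counting exactly", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(roc_auc(c(0, 1), c(0.1, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5) # all ties
  set.seed(505)
  for (r in 1:100) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(round(runif(n), 2)) # coarse scores force ties
    expect_identical(roc_auc(y, s), auc_oracle(y, s))
  }
  expect_warning(a <- roc_auc(c(1, 1), c(0.2, 0.3)), "single-class")
  expect_true(is.na(a))
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (r in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(40)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("average precision matches the step-integration oracle", {
  expect_equal(pr_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)),
               ap_oracle(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)))
  expect_equal(pr_auc(c(0, 1), c(0.1, 0.9)), 1)
  set.seed(606)
  for (r in 1:100) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(round(runif(n), 2))
    expect_equal(pr_auc(y, s), ap_oracle(y, s), tolerance = 1e-12)
  }
  expect_warning(a <- pr_auc(c(1, 1), c(0.2, 0.3)), "single-class")
  expect_true(is.na(a))
})

test_that("cross-validation pools out-of-fold predictions over every miRNA", {
  setup <- tiny_model_setup()
  cv <- cross_validate(setup$input, setup$config, k = 4L)
  expect_s3_class(cv, "milocfuse_cv")
  expect_equal(nrow(cv$per_class), 7)
  expect_identical(cv$per_class$compartment, compartments())
  expect_false(anyNA(cv$probs))
  expect_equal(sort(unique(cv$fold_assignments)), 1:4)
  expect_equal(cv$mean_auc, mean(cv$per_class$auc), tolerance = 1e-12)
  expect_equal(cv$mean_aupr, mean(cv$per_class$aupr), tolerance = 1e-12)
  # tidy/glance/autoplot surfaces
  expect_identical(tidy(cv), cv$per_class)
  g <- glance(cv)
  expect_equal(g$k, 4L)
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("cross-validation is reproducible for a fixed seed", {
  setup <- tiny_model_setup()
  cv1 <- cross_validate(setup$input, setup$config, k = 3L)
  cv2 <- cross_validate(setup$input, setup$config, k = 3L)
  expect_identical(cv1$probs, cv2$probs)
  expect_identical(cv1$per_class, cv2$per_class)
})

test_that("held-out evaluation never trains on the test rows", {
  setup <- tiny_model_setup()
  res <- independent_test(setup$input, setup$config, test_idx = 31:40)
  expect_equal(dim(res$probs), c(10, 7))
  expect_true(all(res$per_class$auc >= 0 & res$per_class$auc <= 1, na.rm = TRUE))
})

test_that("ablation and layer-sweep drivers run one CV per variant", {
  fx <- tiny_features()
  b <- tiny_bundle()
  cfg <- model_config(d_model = 8L, n_heads = 2L, epochs = 6L,
                      batch_size = 16L, hg_layers = 1L, seed = 4L)
  tab <- run_ablation(fx$features, fx$hypergraphs, b$labels, cfg,
                      flag_sets = list(character(0), "no_cross_attention"),
                      k = 3L)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$flags, c("", "no_cross_attention"))
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))
  sw <- sweep_hg_layers(fx$features, fx$hypergraphs, b$labels, cfg,
                        layers = 1:2, k = 3L)
  expect_equal(sw$hg_layers, 1:2)
})
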
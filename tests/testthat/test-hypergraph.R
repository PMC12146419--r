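test_that("incidence construction groups similar and co-associated miRNAs", {
  ids <- c("m1", "m2", "m3")
  sv <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3)
  sim <- similarity_matrix(ids, sv)
  net <- assoc_network(ids, "d1", "disease", matrix(c(1, 1, 1), 3))
  hg <- build_incidence(sim, net, tau = 0.5, top_k = NULL)
  # one similarity hyperedge {m1, m2} (deduplicated) + one association edge
  expect_equal(ncol(hg$incidence), 2)
  expect_equal(sort(colSums(as.matrix(hg$incidence))), c(2, 3))
  # the association hyperedge contains exactly the linked miRNAs
  acol <- which(startsWith(hg$edge_labels, "assoc:"))
  expect_equal(unname(as.matrix(hg$incidence)[, acol]), c(1, 1, 1))
})

test_that("degenerate inputs fail loudly; top-k fallback keeps nodes covered", {
  ids <- c("m1", "m2")
  sim <- similarity_matrix(ids, diag(2))
  net0 <- assoc_network(ids, "d1", "disease", matrix(0, 2, 1))
  expect_error(build_incidence(sim, net0, tau = 0.5), "no hyperedge")
  # positive similarity below tau: fallback picks the top-k neighbours
  simv <- matrix(c(1, 0.2, 0.2, 1), 2)
  hg <- build_incidence(similarity_matrix(ids, simv), net0, tau = 0.5,
                        top_k = 1L)
  expect_equal(ncol(hg$incidence), 1)
  expect_equal(unname(as.matrix(hg$incidence)[, 1]), c(1, 1))
})

test_that("normalised operator matches the dense formula on random hypergraphs", {
  set.seed(404)
  for (r in 1:50) {
    n <- sample(5:20, 1)
    m <- sample(2:8, 1)
    H <- matrix(rbinom(n * m, 1, 0.4), n, m)
    # enforce hyperedges of size >= 2
    for (j in seq_len(m)) {
      while (sum(H[, j]) < 2) H[sample(n, 2), j] <- 1
    }
    w <- runif(m, 0.5, 2)
    hg <- structure(list(node_ids = paste0("x", seq_len(n)),
                         incidence = Matrix::Matrix(H, sparse = TRUE),
                         edge_weights = w,
                         edge_labels = paste0("assoc:e", seq_len(m))),
                    class = "hypergraph")
    a_hat <- as.matrix(normalized_operator(hg))
    expect_equal(unname(a_hat), hg_operator_oracle(H, w), tolerance = 1e-12)
    # symmetry and spectral radius at most 1 (+ tiny numerical slack)
    expect_equal(a_hat, t(a_hat), tolerance = 1e-12)
    expect_lte(max(abs(eigen(a_hat, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("the 2-node operator smooths towards the shared mean", {
  ids <- c("m1", "m2")
  hg <- structure(list(node_ids = ids,
                       incidence = Matrix::Matrix(matrix(1, 2, 1), sparse = TRUE),
                       edge_weights = 1, edge_labels = "assoc:d1"),
                  class = "hypergraph")
  a_hat <- normalized_operator(hg)
  expect_equal(unname(as.matrix(a_hat)), matrix(0.5, 2, 2))
  expect_equal(unname(hgconv_forward(a_hat, matrix(c(2, 4), 2, 1),
                                     list(matrix(1)))),
               matrix(c(3, 3), 2, 1))
})

test_that("nodes in no hyperedge pass through via the identity patch", {
  H <- rbind(c(1), c(1), c(0))
  hg <- structure(list(node_ids = c("a", "b", "c"),
                       incidence = Matrix::Matrix(H, sparse = TRUE),
                       edge_weights = 1, edge_labels = "assoc:e1"),
                  class = "hypergraph")
  a_hat <- as.matrix(normalized_operator(hg))
  expect_equal(unname(a_hat[3, ]), c(0, 0, 1))
  x <- matrix(rnorm(3), 3, 1)
  out <- hgconv_forward(a_hat, x, list(matrix(1)))
  expect_equal(unname(out[3, 1]), x[3, 1])
})

test_that("hgconv layers compose with ReLU on hidden layers only", {
  # identity operator + identity weights: nonnegative input is a fixed point
  a_hat <- Matrix::Diagonal(3)
  x <- matrix(abs(rnorm(9)), 3, 3)
  expect_equal(hgconv_forward(a_hat, x, list(diag(3))), x, ignore_attr = TRUE)
  # zero input stays zero through any weights
  w <- list(matrix(rnorm(9), 3), matrix(rnorm(9), 3))
  expect_equal(hgconv_forward(a_hat, matrix(0, 3, 3), w),
               matrix(0, 3, 3), ignore_attr = TRUE)
  # a negative-only final layer is NOT clipped (linear final layer)
  wneg <- list(-diag(3))
  expect_lt(min(hgconv_forward(a_hat, x, wneg)), 0)
  expect_error(hgconv_forward(a_hat, x, list(matrix(0, 4, 2))),
               "shape mismatch")
})

test_that("hgconv output rows permute with the node order (equivariance)", {
  set.seed(11)
  n <- 6
  H <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  for (j in 1:3) while (sum(H[, j]) < 2) H[sample(n, 2), j] <- 1
  hg <- structure(list(node_ids = paste0("x", 1:n),
                       incidence = Matrix::Matrix(H, sparse = TRUE),
                       edge_weights = rep(1, 3),
                       edge_labels = paste0("assoc:e", 1:3)),
                  class = "hypergraph")
  a_hat <- as.matrix(normalized_operator(hg))
  x <- matrix(rnorm(n * 4), n, 4)
  w <- list(matrix(rnorm(8), 4, 2))
  perm <- sample(n)
  out <- hgconv_forward(a_hat, x, w)
  out_p <- hgconv_forward(a_hat[perm, perm], x[perm, , drop = FALSE], w)
  expect_equal(out_p, out[perm, , drop = FALSE], tolerance = 1e-12)
})
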
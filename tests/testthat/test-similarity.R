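test_that("Smith-Waterman equals the full-DP oracle on random pairs, exactly", {
  set.seed(101)
  schemes <- list(scoring_scheme(), scoring_scheme(3, -3, -2, -2),
                  scoring_scheme(2, -1, -3, -1))
  for (i in seq_len(200)) {
    a <- random_rna(sample(5:30, 1))
    b <- random_rna(sample(5:30, 1))
    s <- schemes[[(i %% 3) + 1]]
    expect_identical(smith_waterman_score(a, b, s),
                     sw_oracle(a, b, s$match, s$mismatch, s$gap_open,
                               s$gap_extend))
  }
})

test_that("Smith-Waterman micro-examples and symmetry", {
  expect_identical(smith_waterman_score("ACGU", "ACGU",
                                        scoring_scheme(1, -1, -2, -2)), 4)
  expect_identical(smith_waterman_score("AAAA", "CCCC",
                                        scoring_scheme(1, -1, -2, -2)), 0)
  # classic textbook instance: score 13 under match 3 / mismatch -3 / gap -2
  expect_identical(smith_waterman_score("UGUUACGG", "GGUUGACUA",
                                        scoring_scheme(3, -3, -2, -2)), 13)
  set.seed(7)
  for (i in 1:20) {
    a <- random_rna(12); b <- random_rna(15)
    expect_identical(smith_waterman_score(a, b), smith_waterman_score(b, a))
  }
  expect_error(smith_waterman_score("", "ACGU"), "empty")
})

test_that("sequence similarity matrix is the normalised score with unit diagonal", {
  # sp("ACGU","AAAA") = 1 (single match), self scores 4 -> similarity 1/4
  m <- mirna_set(c("x", "y"), c(x = "ACGU", y = "AAAA"))
  sw <- sequence_similarity_matrix(m, scoring_scheme(1, -1, -2, -2))
  expect_equal(sw$values["x", "y"], 0.25)
  expect_equal(diag(sw$values), c(x = 1, y = 1))
  # random 22-mers match the oracle matrix entrywise
  set.seed(42)
  ids <- paste0("m", 1:5)
  seqs <- setNames(vapply(1:5, function(i) random_rna(22), character(1)), ids)
  sw2 <- sequence_similarity_matrix(mirna_set(ids, seqs))
  sp <- outer(seq_along(ids), seq_along(ids),
              Vectorize(function(i, j) sw_oracle(seqs[i], seqs[j])))
  expect_equal(unname(sw2$values), sp / sqrt(outer(diag(sp), diag(sp))),
               tolerance = 1e-12)
})

test_that("semantic contributions decay by shortest ancestor layer", {
  dag <- disease_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  sv <- semantic_contributions(dag, "A", 0.5)
  expect_equal(unclass(sv)[c("A", "B", "C")], c(A = 1, B = 0.5, C = 0.25))
  expect_equal(semantic_value(sv), 1.75)
  # diamond: two length-2 routes, contribution delta^2 once
  dd <- disease_dag(c("A", "B", "C", "D"),
                    rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
  svd <- semantic_contributions(dd, "A", 0.5)
  expect_equal(unclass(svd)[["D"]], 0.25)
  expect_equal(semantic_value(svd), 2.25)
  # shortest layer wins when paths of different lengths coexist
  dg <- disease_dag(c("A", "B", "C", "D"),
                    rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D")))
  expect_equal(unclass(semantic_contributions(dg, "A", 0.5))[["D"]], 0.5)
  expect_error(semantic_contributions(dag, "Z"), "unknown disease")
})

test_that("disease semantic similarity matches exhaustive BFS evaluation", {
  dag <- disease_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_equal(disease_semantic_similarity(dag, "A", "B"), 2.25 / 3.25,
               tolerance = 1e-12)
  expect_equal(disease_semantic_similarity(dag, "A", "A"), 1)
  # disjoint components share no ancestor
  dag2 <- disease_dag(c("A", "B", "X", "Y"),
                      rbind(c("A", "B"), c("X", "Y")))
  expect_equal(disease_semantic_similarity(dag2, "A", "X"), 0)
  # 50 random DAGs with <= 15 nodes against the oracle
  set.seed(202)
  for (r in 1:50) {
    g <- random_dag_edges(sample(3:15, 1))
    dag <- disease_dag(g$ids, g$edges)
    pair <- sample(g$ids, 2)
    expect_equal(disease_semantic_similarity(dag, pair[1], pair[2]),
                 dss_oracle(g$edges, pair[1], pair[2]), tolerance = 1e-12)
    expect_equal(disease_semantic_similarity(dag, pair[1], pair[2]),
                 disease_semantic_similarity(dag, pair[2], pair[1]),
                 tolerance = 1e-12)
  }
})

test_that("disease-set similarity takes the max (or mean) over the set", {
  dag <- disease_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_equal(disease_set_similarity(dag, "A", c("A", "C")), 1)
  expect_equal(disease_set_similarity(dag, "A", "B"), 2.25 / 3.25,
               tolerance = 1e-12)
  expect_equal(disease_set_similarity(dag, "A", c("B", "C"), method = "mean"),
               mean(c(disease_semantic_similarity(dag, "A", "B"),
                      disease_semantic_similarity(dag, "A", "C"))),
               tolerance = 1e-12)
  expect_error(disease_set_similarity(dag, "A", character(0)), "empty")
})

test_that("functional similarity follows the set-pair average", {
  dag <- disease_dag(c("A", "B", "C", "X"), rbind(c("A", "B"), c("B", "C")))
  mk <- function(adj) assoc_network(paste0("m", seq_len(nrow(adj))),
                                    c("A", "B", "C", "X"), "disease", adj)
  # identical singleton sets -> 1; disjoint-component sets -> 0
  net <- mk(rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1)))
  fs <- functional_similarity_matrix(dag, net)
  expect_equal(fs$values[1, 2], 1)
  expect_equal(fs$values[1, 3], 0)
  # DT1 = {A}, DT2 = {B} on the chain: (S(A,{B}) + S(B,{A})) / 2 = DSS(A,B)
  net2 <- mk(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  fs2 <- functional_similarity_matrix(dag, net2)
  expect_equal(fs2$values[1, 2], 2.25 / 3.25, tolerance = 1e-12)
  # empty-annotation miRNAs: zero off-diagonal, unit diagonal
  net3 <- mk(rbind(c(1, 0, 0, 0), c(0, 0, 0, 0)))
  fs3 <- functional_similarity_matrix(dag, net3)
  expect_equal(fs3$values[1, 2], 0)
  expect_equal(diag(fs3$values), c(m1 = 1, m2 = 1))
  # disease absent from the DAG is a hard error naming it
  net4 <- assoc_network("m1", "ZZ", "disease", matrix(1))
  expect_error(functional_similarity_matrix(dag, net4), "ZZ")
})

test_that("GIP kernel equals its entrywise formula", {
  net <- assoc_network(c("m1", "m2"), c("d1", "d2"), "disease", diag(2))
  gip <- gip_similarity_matrix(net)
  expect_equal(gip$values[1, 2], exp(-2), tolerance = 1e-12)
  # identical profiles have similarity exactly 1
  net2 <- assoc_network(c("m1", "m2"), c("d1", "d2"), "disease",
                        rbind(c(1, 0), c(1, 0)))
  expect_equal(gip_similarity_matrix(net2)$values[1, 2], 1)
  # random instances against the literal oracle
  set.seed(303)
  for (r in 1:20) {
    Y <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5)
    if (sum(Y) == 0) Y[1, 1] <- 1
    net <- assoc_network(paste0("m", 1:8), paste0("d", 1:5), "disease", Y)
    expect_equal(unname(gip_similarity_matrix(net)$values), gip_oracle(Y),
                 tolerance = 1e-12)
  }
  # larger bandwidth shrinks every off-diagonal with nonzero distance
  Y <- diag(4)
  net <- assoc_network(paste0("m", 1:4), paste0("d", 1:4), "disease", Y)
  g1 <- gip_similarity_matrix(net, 1)$values
  g2 <- gip_similarity_matrix(net, 2)$values
  off <- upper.tri(g1)
  expect_true(all(g2[off] < g1[off]))
  zero <- assoc_network("m1", "d1", "disease", matrix(0))
  expect_error(gip_similarity_matrix(zero), "all-zero")
})

test_that("similarity fusion picks FS where positive, else GIP", {
  ids <- c("a", "b", "c")
  fsv <- matrix(c(1, 0.3, 0, 0.3, 1, 0, 0, 0, 1), 3)
  gipv <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.4, 0.2, 0.4, 1), 3)
  fused <- fuse_similarities(similarity_matrix(ids, fsv),
                             similarity_matrix(ids, gipv))
  expect_equal(fused$values["a", "b"], 0.3)
  expect_equal(fused$values["a", "c"], 0.2)
  # every output entry comes from one of the inputs
  pick <- fused$values == fsv | fused$values == gipv
  expect_true(all(pick))
  expect_equal(fused$values, t(fused$values))
  expect_error(fuse_similarities(similarity_matrix(ids, fsv),
                                 similarity_matrix(c("x", "y", "z"), gipv)),
               "id mismatch")
})

test_that("constructed similarity matrices satisfy the shared invariants", {
  b <- tiny_bundle()
  fx <- tiny_features()
  for (s in fx$similarities) {
    v <- s$values
    expect_lte(max(abs(v - t(v))), 1e-9)
    expect_equal(unname(diag(v)), rep(1, nrow(v)))
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
  }
})
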
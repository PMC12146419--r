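# Node2vec embedding of bipartite association networks: biased second-order
# random walks plus skip-gram with negative sampling. Both stages draw all
# randomness from R's RNG, so a single set.seed() makes them reproducible.

#' Node2vec hyperparameters
#'
#' Embedding dimension 128 matches the feature width used throughout the
#' model; the remaining defaults are the standard node2vec settings
#' (`p = q = 1`, 10 walks of length 80 per node, window 10, 5 epochs,
#' 5 negative samples).
#'
#' @param dim Embedding dimension.
#' @param num_walks Walks started per node.
#' @param walk_length Maximum walk length (shorter only at isolated nodes).
#' @param window Skip-gram context window (actual window sampled in
#'   `1..window` per position).
#' @param p Return parameter (weight `1/p` for revisiting the previous node).
#' @param q In-out parameter (weight `1/q` for distance-2 moves).
#' @param epochs Skip-gram training epochs.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (linearly decayed to `min_alpha`).
#' @param min_alpha Final learning rate.
#' @return An object of class `node2vec_params`.
#' @export
node2vec_params <- function(dim = 128L, num_walks = 10L, walk_length = 80L,
                            window = 10L, p = 1, q = 1, epochs = 5L,
                            negative = 5L, alpha = 0.025, min_alpha = 1e-4) {
  stopifnot(dim > 0, num_walks > 0, walk_length >= 2, p > 0, q > 0,
            window >= 1, epochs >= 1, negative >= 1)
  structure(list(dim = as.integer(dim), num_walks = as.integer(num_walks),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window), p = p, q = q,
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, min_alpha = min_alpha),
            class = "node2vec_params")
}

#' Build the undirected bipartite graph of an association network
#'
#' miRNAs and entities become nodes (namespaced as `mirna:<id>` and
#' `<kind>:<id>` to avoid collisions); each adjacency 1 becomes one
#' undirected, unweighted edge.
#'
#' @param assoc An [assoc_network()].
#' @return An [igraph::graph] object.
#' @export
build_bipartite_graph <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_network"))
  mn <- paste0("mirna:", assoc$mirna_ids)
  en <- paste0(assoc$entity_kind, ":", assoc$entity_ids)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(mn) + length(en), name = c(mn, en))
  idx <- which(assoc$adjacency == 1, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    edges <- rbind(mn[idx[, 1]], en[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(edges))
  }
  g
}

#' Generate biased second-order random walks
#'
#' `num_walks` walks per node; transition weights are `1/p` back to the
#' previous node, 1 to common neighbours of the previous node, and `1/q`
#' otherwise, normalised per step. Isolated nodes yield length-1 walks.
#'
#' @param graph An undirected [igraph::graph] with named vertices.
#' @param params A [node2vec_params()].
#' @return List of character vectors (walks as node names).
#' @export
biased_random_walks <- function(graph, params = node2vec_params()) {
  stopifnot(igraph::vcount(graph) > 0)
  nm <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                function(v) as.integer(v) - 1L)
  walks <- .node2vec_walks_cpp(adj, params$num_walks, params$walk_length,
                               params$p, params$q)
  lapply(walks, function(w) nm[w + 1L])
}

#' Train skip-gram embeddings over random walks
#'
#' Skip-gram with negative sampling; deterministic for a fixed RNG seed
#' (single-threaded SGD). Nodes never seen in a (center, context) pair keep a
#' zero vector, reported via a message.
#'
#' @param walks List of walks as returned by [biased_random_walks()].
#' @param nodes Character vector of all graph node names (every node gets a
#'   row, visited or not).
#' @param params A [node2vec_params()].
#' @return Numeric `length(nodes)` x `dim` matrix, rows named by node.
#' @export
skipgram_embed <- function(walks, nodes, params = node2vec_params()) {
  stopifnot(length(walks) > 0)
  idx_walks <- lapply(walks, function(w) match(w, nodes) - 1L)
  if (anyNA(unlist(idx_walks, use.names = FALSE))) {
    stop("skipgram_embed: walk visits a node outside `nodes`")
  }
  emb <- .sgns_embed_cpp(idx_walks, length(nodes), params$dim, params$window,
                         params$epochs, params$negative, params$alpha,
                         params$min_alpha)
  rownames(emb) <- nodes
  untrained <- rowSums(abs(emb)) == 0
  if (any(untrained)) {
    message("skipgram_embed: ", sum(untrained),
            " node(s) never visited; zero vectors assigned")
  }
  emb
}

#' Embed one association network and return the miRNA feature block
#'
#' Composes [build_bipartite_graph()], [biased_random_walks()] and
#' [skipgram_embed()], returning only the miRNA rows in canonical order.
#' miRNAs absent from the graph (all-zero adjacency rows) get zero vectors.
#'
#' @param assoc An [assoc_network()].
#' @param params A [node2vec_params()].
#' @param seed Optional integer seed applied just before walk generation.
#' @return A [feature_matrix()] with branch matching the entity kind.
#' @export
embed_network <- function(assoc, params = node2vec_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- build_bipartite_graph(assoc)
  walks <- biased_random_walks(g, params)
  emb <- skipgram_embed(walks, igraph::V(g)$name, params)
  rows <- paste0("mirna:", assoc$mirna_ids)
  branch <- c(disease = "disease", drug = "drug", mrna = "mrna_net")[[assoc$entity_kind]]
  feature_matrix(assoc$mirna_ids, emb[rows, , drop = FALSE], branch)
}
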
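# miRNA hypergraphs: similarity- and association-derived hyperedges, and the
# normalised hypergraph convolution operator used to refine node2vec features.

#' Build a miRNA hypergraph from similarity and association evidence
#'
#' Two families of hyperedges: one per miRNA `i` collecting
#' `{i} + {j : sim(i, j) >= tau}` (if no other miRNA reaches `tau`, the
#' `top_k` most similar miRNAs with positive similarity are used instead, so
#' every node stays covered); and one per entity collecting the miRNAs
#' associated with it. Hyperedges with fewer than 2 members are dropped and
#' duplicated member sets are collapsed to a single column. All hyperedge
#' weights are 1.
#'
#' @param sim A [similarity_matrix()] over the miRNAs.
#' @param assoc An [assoc_network()] with the same miRNA order.
#' @param tau Similarity threshold in `(0, 1)`.
#' @param top_k Fallback neighbourhood size for rows with no neighbour at
#'   `tau` (`NULL` disables the fallback).
#' @return An object of class `hypergraph` with fields `node_ids`,
#'   `incidence` (sparse), `edge_weights` and `edge_labels`.
#' @export
build_incidence <- function(sim, assoc, tau = 0.5, top_k = 5L) {
  stopifnot(inherits(sim, "similarity_matrix"), inherits(assoc, "assoc_network"),
            tau > 0, tau < 1)
  if (!identical(sim$ids, assoc$mirna_ids)) {
    stop("build_incidence: similarity and association miRNA orders differ")
  }
  n <- length(sim$ids)
  S <- sim$values
  members <- list()
  labels <- character(0)
  for (i in seq_len(n)) {
    nb <- which(S[i, ] >= tau)
    nb <- setdiff(nb, i)
    if (length(nb) == 0 && !is.null(top_k)) {
      pos <- which(S[i, ] > 0)
      pos <- setdiff(pos, i)
      if (length(pos) > 0) {
        nb <- pos[order(S[i, pos], decreasing = TRUE)][seq_len(min(top_k, length(pos)))]
      }
    }
    if (length(nb) > 0) {
      members[[length(members) + 1]] <- sort(c(i, nb))
      labels <- c(labels, paste0("sim:", sim$ids[i]))
    }
  }
  for (j in seq_along(assoc$entity_ids)) {
    mem <- which(assoc$adjacency[, j] == 1)
    if (length(mem) >= 2) {
      members[[length(members) + 1]] <- sort(mem)
      labels <- c(labels, paste0("assoc:", assoc$entity_ids[j]))
    }
  }
  if (length(members) == 0) {
    stop("build_incidence: no hyperedge of size >= 2 survives; lower tau")
  }
  keys <- vapply(members, paste, character(1), collapse = ",")
  keep <- !duplicated(keys)
  members <- members[keep]
  labels <- labels[keep]
  H <- Matrix::sparseMatrix(
    i = unlist(members, use.names = FALSE),
    j = rep(seq_along(members), lengths(members)),
    x = 1, dims = c(n, length(members))
  )
  rownames(H) <- sim$ids
  structure(list(node_ids = sim$ids, incidence = H,
                 edge_weights = rep(1, length(members)), edge_labels = labels),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("<hypergraph> ", length(x$node_ids), " nodes, ", ncol(x$incidence),
      " hyperedges (", sum(startsWith(x$edge_labels, "sim:")), " similarity, ",
      sum(startsWith(x$edge_labels, "assoc:")), " association)\n", sep = "")
  invisible(x)
}

#' Normalised hypergraph convolution operator
#'
#' `A_hat = Dv^-1/2 H W B^-1 H' Dv^-1/2`, where `B` holds hyperedge degrees
#' (column sums of `H`) and `Dv` node degrees (row sums of `H W`). Nodes in
#' no hyperedge get an identity row/column so their features pass through the
#' convolution unchanged. `A_hat` is symmetric with non-negative entries and
#' spectral radius at most 1.
#'
#' @param hg A `hypergraph` from [build_incidence()].
#' @return A sparse symmetric matrix (class `dgCMatrix`).
#' @export
normalized_operator <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- hg$incidence
  w <- hg$edge_weights
  stopifnot(all(w > 0), all(Matrix::colSums(H) >= 2))
  b <- Matrix::colSums(H)
  dv <- as.numeric(H %*% w)
  inv_sqrt <- ifelse(dv > 0, 1 / sqrt(dv), 0)
  Hw <- H %*% Matrix::Diagonal(x = w / b)
  core <- Matrix::Diagonal(x = inv_sqrt) %*% Hw %*% Matrix::t(H) %*%
    Matrix::Diagonal(x = inv_sqrt)
  iso <- which(dv == 0)
  if (length(iso) > 0) core <- core + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                                           dims = dim(core))
  out <- methods::as(core, "CsparseMatrix")
  dimnames(out) <- list(hg$node_ids, hg$node_ids)
  out
}

#' Multi-layer hypergraph convolution forward pass
#'
#' `H^(l+1) = act(A_hat H^(l) W^(l))` with ReLU on hidden layers and a linear
#' final layer, so downstream fusion sees signed features.
#'
#' @param a_hat Operator from [normalized_operator()].
#' @param x0 Numeric input matrix (nodes x features).
#' @param weights List of layer weight matrices with chain-compatible shapes.
#' @return Numeric matrix (nodes x `ncol(last weight)`).
#' @export
hgconv_forward <- function(a_hat, x0, weights) {
  z <- as.matrix(x0)
  L <- length(weights)
  for (l in seq_len(L)) {
    if (ncol(z) != nrow(weights[[l]])) {
      stop("hgconv_forward: shape mismatch at layer ", l)
    }
    z <- as.matrix(a_hat %*% (z %*% weights[[l]]))
    if (l < L) z <- pmax(z, 0)
  }
  z
}
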
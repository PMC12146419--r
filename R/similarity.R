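# Intrinsic miRNA similarities: Smith-Waterman sequence similarity,
# disease-ontology semantic -> miRNA functional similarity, the Gaussian
# interaction-profile (GIP) kernel, and the FS/GIP fusion rule.

#' Nucleotide scoring scheme for local alignment
#'
#' Alignment parameter choices vary widely across miRNA similarity
#' pipelines; the defaults here are common nucleotide settings (match +1,
#' mismatch -1, affine gaps -2/-1). The self-normalisation in
#' [sequence_similarity_matrix()] bounds the similarity in `[0, 1]`
#' regardless of the scheme.
#'
#' @param match Positive match score.
#' @param mismatch Non-positive mismatch score.
#' @param gap_open Non-positive score for the first position of a gap.
#' @param gap_extend Non-positive score for each subsequent gap position.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -2,
                           gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

check_rna <- function(x) {
  if (any(nchar(x) == 0)) stop("empty sequence")
  if (any(grepl("[^ACGU]", x))) stop("sequence contains characters outside {A,C,G,U}")
  x
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score with affine gaps: a gap of length L costs
#' `-(gap_open + (L - 1) * gap_extend)`. The score is non-negative and
#' symmetric in its arguments.
#'
#' @param a,b RNA sequences over `{A,C,G,U}`.
#' @param scheme A [scoring_scheme()].
#' @return The alignment score (a single non-negative number).
#' @export
#' @examples
#' smith_waterman_score("ACGU", "ACGU")
smith_waterman_score <- function(a, b, scheme = scoring_scheme()) {
  check_rna(c(a, b))
  .sw_score_cpp(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
                scheme$gap_extend)
}

#' Smith-Waterman sequence-similarity matrix
#'
#' `SW(i, j) = sp(i, j) / sqrt(sp(i, i) * sp(j, j))` where `sp` is the local
#' alignment score; the diagonal is exactly 1 and all values lie in `[0, 1]`.
#'
#' @param m A [mirna_set()].
#' @param scheme A [scoring_scheme()].
#' @return A [similarity_matrix()] over the miRNA ids.
#' @export
sequence_similarity_matrix <- function(m, scheme = scoring_scheme()) {
  stopifnot(inherits(m, "mirna_set"))
  check_rna(m$sequences)
  sp <- .sw_score_matrix_cpp(unname(m$sequences[m$ids]), scheme$match,
                             scheme$mismatch, scheme$gap_open,
                             scheme$gap_extend)
  self <- diag(sp)
  stopifnot(all(self > 0)) # guaranteed since match > 0
  sw <- sp / sqrt(outer(self, self))
  diag(sw) <- 1
  similarity_matrix(m$ids, sw)
}

# ---- disease semantic similarity --------------------------------------------

#' Semantic contributions of a disease's ancestors
#'
#' Each ancestor `t` of anchor disease `A` contributes `delta^k`, where `k`
#' is the length of the shortest child-to-parent path from `A` to `t`
#' (the "smallest layer"); the anchor itself contributes 1.
#'
#' @param dag A [disease_dag()].
#' @param anchor Disease identifier present in `dag`.
#' @param delta Decay factor in `(0, 1)`; 0.5 follows common usage for
#'   MeSH-style semantic similarity.
#' @return Named numeric vector of contributions over the ancestor closure,
#'   with attribute `anchor`; class `semantic_values`.
#' @export
semantic_contributions <- function(dag, anchor, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  if (!anchor %in% dag$nodes) stop("unknown disease: ", anchor)
  depth <- c(stats::setNames(0L, anchor))
  frontier <- anchor
  k <- 0L
  while (length(frontier) > 0) {
    k <- k + 1L
    nxt <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                   names(depth))
    if (length(nxt) > 0) depth[nxt] <- k
    frontier <- nxt
  }
  structure(delta^depth, anchor = anchor, class = "semantic_values")
}

#' Semantic value of a disease
#'
#' The sum of the contributions of the disease and all its ancestors;
#' always at least 1.
#'
#' @param sv A `semantic_values` object from [semantic_contributions()].
#' @return A single number.
#' @export
semantic_value <- function(sv) {
  stopifnot(inherits(sv, "semantic_values"))
  sum(unclass(sv))
}

#' Semantic similarity of two diseases
#'
#' Shared-ancestor similarity: the summed contributions each disease assigns
#' to the common part of their ancestor closures, normalised by the two
#' semantic values. Symmetric, in `[0, 1]`, with `DSS(A, A) = 1`.
#'
#' @param dag A [disease_dag()].
#' @param a,b Disease identifiers.
#' @param delta Decay factor, see [semantic_contributions()].
#' @return A single number in `[0, 1]`.
#' @export
disease_semantic_similarity <- function(dag, a, b, delta = 0.5) {
  sva <- semantic_contributions(dag, a, delta)
  svb <- semantic_contributions(dag, b, delta)
  common <- intersect(names(sva), names(svb))
  if (length(common) == 0) return(0)
  sum(unclass(sva)[common] + unclass(svb)[common]) /
    (semantic_value(sva) + semantic_value(svb))
}

#' Similarity between a disease and a disease set
#'
#' Several definitions of disease-to-set similarity are in use; the
#' standard choice in this literature, the maximum pairwise semantic
#' similarity over the set, is the default, with `"mean"` exposed as an
#' alternative.
#'
#' @param dag A [disease_dag()].
#' @param d Disease identifier.
#' @param dt Non-empty character vector of diseases.
#' @param delta Decay factor.
#' @param method `"max"` (default) or `"mean"`.
#' @return A single number in `[0, 1]`.
#' @export
disease_set_similarity <- function(dag, d, dt, delta = 0.5,
                                   method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(dt) == 0) stop("disease_set_similarity: empty disease set")
  vals <- vapply(dt, function(t) disease_semantic_similarity(dag, d, t, delta),
                 numeric(1))
  if (method == "max") max(vals) else mean(vals)
}

# Pairwise DSS over a fixed disease vocabulary, vectorised over the sparse
# contribution matrix: num(A,B) = sum_t in TA^TB (SV_A(t) + SV_B(t)).
dss_matrix <- function(dag, diseases, delta = 0.5) {
  nd <- length(diseases)
  if (nd == 0) return(matrix(0, 0, 0))
  anc <- lapply(diseases, function(d) semantic_contributions(dag, d, delta))
  vocab <- unique(unlist(lapply(anc, names), use.names = FALSE))
  P <- matrix(0, nd, length(vocab), dimnames = list(diseases, vocab))
  for (i in seq_len(nd)) P[i, names(anc[[i]])] <- unclass(anc[[i]])
  M <- (P > 0) * 1
  num <- P %*% t(M) + M %*% t(P)
  sem <- rowSums(P)
  dss <- num / outer(sem, sem, `+`)
  diag(dss) <- 1
  dss
}

#' miRNA functional-similarity matrix from disease annotations
#'
#' For miRNAs annotated with disease sets DT1 (size n1) and DT2 (size n2),
#' `FS = (sum_i S(dt1_i, DT2) + sum_j S(dt2_j, DT1)) / (n1 + n2)` where `S`
#' is [disease_set_similarity()]. miRNAs with no disease annotation get an
#' all-zero off-diagonal row (the fusion rule then falls back to the GIP
#' kernel for them); the diagonal is always 1.
#'
#' @param dag A [disease_dag()].
#' @param assoc An [assoc_network()] with `entity_kind = "disease"`; every
#'   disease must be a node of `dag`.
#' @param delta Decay factor.
#' @param method Set-similarity mode, see [disease_set_similarity()].
#' @return A [similarity_matrix()] over the miRNA ids.
#' @export
functional_similarity_matrix <- function(dag, assoc, delta = 0.5,
                                         method = c("max", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(assoc, "assoc_network"))
  if (assoc$entity_kind != "disease") {
    stop("functional_similarity_matrix: entity_kind must be 'disease'")
  }
  miss <- setdiff(assoc$entity_ids, dag$nodes)
  if (length(miss) > 0) {
    stop("functional_similarity_matrix: disease not in DAG: ", miss[[1]])
  }
  A <- assoc$adjacency
  n <- nrow(A)
  dss <- dss_matrix(dag, assoc$entity_ids, delta)
  sizes <- rowSums(A)
  # maxS[d, m] = S(d, DT_m): best (or mean) similarity of disease d to m's set
  FS <- matrix(0, n, n)
  nonempty <- which(sizes > 0)
  if (length(nonempty) > 0) {
    maxS <- matrix(0, ncol(A), n)
    for (m in nonempty) {
      sub <- dss[, A[m, ] == 1, drop = FALSE]
      maxS[, m] <- if (method == "max") {
        do.call(pmax, c(as.data.frame(sub), list(na.rm = TRUE)))
      } else rowMeans(sub)
    }
    # G[m1, m2] = sum_{d in DT_{m1}} S(d, DT_{m2})
    G <- A %*% maxS
    FS <- (G + t(G)) / outer(sizes, sizes, `+`)
    FS[sizes == 0, ] <- 0
    FS[, sizes == 0] <- 0
  }
  diag(FS) <- 1
  similarity_matrix(assoc$mirna_ids, FS)
}

# ---- GIP kernel --------------------------------------------------------------

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' `GIP(i, j) = exp(-gamma * ||y_i - y_j||^2)` over the rows of the binary
#' association profile, with bandwidth `gamma = gamma_prime / mean_i ||y_i||^2`.
#'
#' @param assoc An [assoc_network()] with at least one edge.
#' @param gamma_prime Bandwidth hyperparameter (default 1, following common
#'   usage for interaction-profile kernels).
#' @return A [similarity_matrix()] over the miRNA ids.
#' @export
gip_similarity_matrix <- function(assoc, gamma_prime = 1) {
  stopifnot(inherits(assoc, "assoc_network"))
  Y <- assoc$adjacency
  sq <- rowSums(Y^2)
  if (sum(sq) == 0) stop("gip_similarity_matrix: all-zero adjacency, bandwidth undefined")
  gamma <- gamma_prime / mean(sq)
  d2 <- outer(sq, sq, `+`) - 2 * (Y %*% t(Y))
  d2[d2 < 0] <- 0
  similarity_matrix(assoc$mirna_ids, exp(-gamma * d2))
}

#' Fuse functional and GIP similarities
#'
#' Entrywise: the functional similarity where it is positive, otherwise the
#' GIP kernel value (which patches the zero entries left by unannotated
#' miRNAs or disjoint disease sets).
#'
#' @param fs,gip [similarity_matrix()] objects with identical id order.
#' @return A [similarity_matrix()].
#' @export
fuse_similarities <- function(fs, gip) {
  stopifnot(inherits(fs, "similarity_matrix"), inherits(gip, "similarity_matrix"))
  if (!identical(fs$ids, gip$ids)) stop("fuse_similarities: id mismatch")
  fused <- ifelse(fs$values > 0, fs$values, gip$values)
  similarity_matrix(fs$ids, fused)
}
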
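# Independent oracles, written as literal transcriptions of the definitions
# and kept deliberately naive (full DP tables, explicit loops) so they share
# no code path with the implementation they check.

# Full-table Gotoh local alignment: gap of length L costs
# -(open + (L - 1) * ext).
sw_oracle <- function(a, b, match = 1, mismatch = -1, open = -2, ext = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + open, E[i, j - 1] + ext)
      F[i, j] <- max(H[i - 1, j] + open, F[i - 1, j] + ext)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H)
}

# Exhaustive ancestor enumeration: layer-by-layer BFS over child->parent
# edges; shortest layer wins. Used to evaluate the contribution, semantic
# value and shared-ancestor similarity definitions literally.
ancestors_oracle <- function(edges, node) {
  depth <- stats::setNames(0L, node)
  frontier <- node
  k <- 0L
  while (length(frontier) > 0) {
    k <- k + 1L
    nxt <- character(0)
    for (f in frontier) {
      if (nrow(edges) > 0) nxt <- c(nxt, edges[edges[, 1] == f, 2])
    }
    nxt <- setdiff(unique(nxt), names(depth))
    if (length(nxt) > 0) depth[nxt] <- k
    frontier <- nxt
  }
  depth
}

dss_oracle <- function(edges, a, b, delta = 0.5) {
  da <- ancestors_oracle(edges, a)
  db <- ancestors_oracle(edges, b)
  sva <- delta^da
  svb <- delta^db
  common <- intersect(names(sva), names(svb))
  if (length(common) == 0) return(0)
  sum(sva[common] + svb[common]) / (sum(sva) + sum(svb))
}

# Literal entrywise evaluation of the interaction-profile kernel.
gip_oracle <- function(Y, gamma_prime = 1) {
  gamma <- gamma_prime / mean(rowSums(Y^2))
  n <- nrow(Y)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- exp(-gamma * sum((Y[i, ] - Y[j, ])^2))
    }
  }
  out
}

# Dense evaluation of Dv^-1/2 H W B^-1 H' Dv^-1/2 with the identity patch
# for nodes in no hyperedge.
hg_operator_oracle <- function(H, w) {
  H <- as.matrix(H)
  B <- diag(colSums(H), ncol(H))
  dv <- as.numeric(H %*% w)
  Dv <- diag(ifelse(dv > 0, 1 / sqrt(dv), 0), nrow(H))
  A <- Dv %*% H %*% diag(w, length(w)) %*% solve(B) %*% t(H) %*% Dv
  for (i in which(dv == 0)) A[i, i] <- 1
  A
}

# Loop-based multi-head scaled dot-product attention over B tokens, one
# sample at a time.
attention_oracle <- function(q_tokens, k_tokens, v_tokens, att, n_heads) {
  B <- length(q_tokens)
  nb <- nrow(q_tokens[[1]])
  d <- ncol(q_tokens[[1]])
  dk <- d / n_heads
  out <- lapply(seq_len(B), function(b) matrix(0, nb, d))
  for (i in seq_len(nb)) {
    Q <- t(vapply(q_tokens, function(m) m[i, ], numeric(d))) %*% att$wq +
      matrix(att$bq, B, d, byrow = TRUE)
    K <- t(vapply(k_tokens, function(m) m[i, ], numeric(d))) %*% att$wk +
      matrix(att$bk, B, d, byrow = TRUE)
    V <- t(vapply(v_tokens, function(m) m[i, ], numeric(d))) %*% att$wv +
      matrix(att$bv, B, d, byrow = TRUE)
    heads <- matrix(0, B, d)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      heads[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    M <- heads %*% att$wo + matrix(att$bo, B, d, byrow = TRUE)
    for (b in seq_len(B)) out[[b]][i, ] <- M[b, ]
  }
  out
}

# Concordant-pair counting AUC with half weight for ties.
auc_oracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Step-integration average precision over decreasing distinct thresholds.
ap_oracle <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  n1 <- sum(y == 1)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    sel <- s >= t
    prec <- sum(y[sel] == 1) / sum(sel)
    rec <- sum(y[sel] == 1) / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Random parent-pointing DAG over n nodes: each node may attach to earlier
# nodes, guaranteeing acyclicity.
random_dag_edges <- function(n, p_edge = 0.4) {
  ids <- sprintf("D%02d", seq_len(n))
  edges <- matrix(character(0), ncol = 2)
  for (i in seq_len(n)[-1]) {
    pars <- which(runif(i - 1) < p_edge)
    if (length(pars) == 0 && runif(1) < 0.8) pars <- sample.int(i - 1, 1)
    for (p in pars) edges <- rbind(edges, c(ids[i], ids[p]))
  }
  list(ids = ids, edges = edges)
}
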
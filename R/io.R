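# Domain containers and plain-text readers/writers.
#
# One unambiguous index space: the miRNA order of the FASTA file is canonical,
# and every network / feature / label object is aligned to it (miRNAs missing
# from a given source keep all-zero rows rather than being dropped).

# ---- miRNA set ---------------------------------------------------------------

#' Construct a miRNA sequence set
#'
#' @param ids Character vector of unique miRNA identifiers.
#' @param sequences Named character vector (names = `ids`) of RNA sequences
#'   over `A`, `C`, `G`, `U`. `T` is accepted and normalised to `U`;
#'   lower case is folded to upper case.
#' @return An object of class `mirna_set` with fields `ids` and `sequences`.
#' @export
mirna_set <- function(ids, sequences) {
  ids <- as.character(ids)
  if (length(ids) == 0) stop("mirna_set: ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("mirna_set: duplicate id ", dup[[1]])
  sequences <- toupper(as.character(sequences))
  sequences <- chartr("T", "U", sequences)
  if (is.null(names(sequences))) names(sequences) <- ids
  sequences <- sequences[ids]
  if (anyNA(sequences)) stop("mirna_set: missing sequence for some ids")
  if (any(nchar(sequences) < 1)) {
    stop("mirna_set: empty sequence for id ",
         ids[which(nchar(sequences) < 1)[[1]]])
  }
  bad <- grepl("[^ACGU]", sequences)
  if (any(bad)) {
    stop("mirna_set: sequence for id ", ids[which(bad)[[1]]],
         " contains characters outside {A,C,G,U}")
  }
  structure(list(ids = ids, sequences = sequences), class = "mirna_set")
}

#' Read miRNA sequences from a FASTA file
#'
#' Record order in the file defines the canonical miRNA order used by every
#' other object in a run. `T` is normalised to `U` and case is folded.
#'
#' @param path Path to a FASTA file.
#' @return A [mirna_set()].
#' @export
read_mirna_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(duplicated(ids))) {
    stop("read_mirna_fasta: duplicate id ", ids[duplicated(ids)][[1]])
  }
  if (any(Biostrings::width(ss) == 0)) {
    stop("read_mirna_fasta: empty record ", ids[Biostrings::width(ss) == 0][[1]])
  }
  mirna_set(ids, setNames(as.character(ss), ids))
}

#' Write a miRNA set to FASTA
#'
#' @param m A [mirna_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(m, path) {
  stopifnot(inherits(m, "mirna_set"))
  writeLines(paste0(">", m$ids, "\n", m$sequences[m$ids]), path)
  invisible(path)
}

#' @export
print.mirna_set <- function(x, ...) {
  cat("<mirna_set> ", length(x$ids), " miRNAs, lengths ",
      min(nchar(x$sequences)), "-", max(nchar(x$sequences)), " nt\n", sep = "")
  invisible(x)
}

# ---- bipartite association networks -----------------------------------------

#' Construct a bipartite miRNA-entity association network
#'
#' @param mirna_ids Ordered miRNA identifiers (the canonical order).
#' @param entity_ids Ordered entity identifiers.
#' @param entity_kind One of `"disease"`, `"drug"`, `"mrna"`.
#' @param adjacency Binary `length(mirna_ids)` x `length(entity_ids)` matrix.
#' @return An object of class `assoc_network`.
#' @export
assoc_network <- function(mirna_ids, entity_ids, entity_kind, adjacency) {
  entity_kind <- match.arg(entity_kind, c("disease", "drug", "mrna"))
  adjacency <- as.matrix(adjacency)
  if (!all(adjacency %in% c(0, 1))) {
    stop("assoc_network: adjacency entries must be 0/1")
  }
  if (nrow(adjacency) != length(mirna_ids) ||
      ncol(adjacency) != length(entity_ids)) {
    stop("assoc_network: adjacency dimensions do not match id lists")
  }
  if (any(duplicated(mirna_ids)) || any(duplicated(entity_ids))) {
    stop("assoc_network: duplicate ids")
  }
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(mirna_ids, entity_ids)
  structure(list(mirna_ids = as.character(mirna_ids),
                 entity_ids = as.character(entity_ids),
                 entity_kind = entity_kind,
                 adjacency = adjacency),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("<assoc_network:", x$entity_kind, "> ", length(x$mirna_ids), " miRNAs x ",
      length(x$entity_ids), " entities, ", sum(x$adjacency), " edges\n", sep = "")
  invisible(x)
}

read_tsv_rows <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a two-column miRNA-entity edge list
#'
#' Tab-separated `mirna_id<TAB>entity_id` rows; `#` comment lines are skipped
#' and an optional `mirna_id entity_id` header is recognised. Edges whose
#' miRNA is outside `mirna_universe` are dropped (a message reports the
#' count); the entity set is the sorted distinct entities that survive.
#' miRNAs of the universe with no surviving edge keep all-zero rows.
#'
#' @param path Path to the TSV edge list.
#' @param entity_kind One of `"disease"`, `"drug"`, `"mrna"`.
#' @param mirna_universe Character vector: the canonical miRNA order.
#' @return An [assoc_network()].
#' @export
read_edge_list <- function(path, entity_kind, mirna_universe) {
  stopifnot(file.exists(path))
  rows <- read_tsv_rows(path)
  parts <- strsplit(rows$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[[1]]
    stop("read_edge_list: malformed row at line ", rows$lineno[bad],
         " (expected 2 tab-separated fields, got ", nf[bad], ")")
  }
  m <- vapply(parts, `[[`, character(1), 1)
  e <- vapply(parts, `[[`, character(1), 2)
  if (length(m) > 0 && m[[1]] == "mirna_id" && e[[1]] == "entity_id") {
    m <- m[-1]; e <- e[-1]
  }
  inside <- m %in% mirna_universe
  dropped <- sum(!inside)
  if (dropped > 0) {
    message("read_edge_list: dropped ", dropped,
            " edge(s) whose miRNA is outside the universe")
  }
  m <- m[inside]; e <- e[inside]
  entities <- sort(unique(e))
  adj <- matrix(0, length(mirna_universe), length(entities),
                dimnames = list(mirna_universe, entities))
  if (length(m) > 0) adj[cbind(m, e)] <- 1
  assoc_network(mirna_universe, entities, entity_kind, adj)
}

#' Write an association network as an edge list
#'
#' @param net An [assoc_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- paste(net$mirna_ids[idx[, 1]], net$entity_ids[idx[, 2]], sep = "\t")
  writeLines(c("mirna_id\tentity_id", lines), path)
  invisible(path)
}

# ---- disease DAG -------------------------------------------------------------

#' Construct a disease DAG from child-parent edges
#'
#' @param nodes Character vector of disease identifiers.
#' @param parent_edges Two-column character matrix (child, parent).
#' @return An object of class `disease_dag` with `nodes`, `parent_edges`
#'   and a parent adjacency list `parents`.
#' @export
disease_dag <- function(nodes, parent_edges) {
  nodes <- unique(as.character(nodes))
  parent_edges <- matrix(as.character(parent_edges), ncol = 2)
  if (nrow(parent_edges) > 0) {
    miss <- setdiff(c(parent_edges), nodes)
    if (length(miss) > 0) stop("disease_dag: edge endpoint not a node: ", miss[[1]])
    if (any(parent_edges[, 1] == parent_edges[, 2])) {
      stop("disease_dag: self-loop at ",
           parent_edges[parent_edges[, 1] == parent_edges[, 2], 1][[1]])
    }
  }
  parents <- split(parent_edges[, 2], factor(parent_edges[, 1], levels = nodes))
  parents <- lapply(parents, unique)
  # Kahn's algorithm on the child -> parent digraph: verify acyclicity
  children <- split(parent_edges[, 1], factor(parent_edges[, 2], levels = nodes))
  indeg_out <- vapply(parents, length, integer(1)) # outgoing child->parent count
  queue <- nodes[indeg_out == 0]
  seen <- 0L
  indeg_work <- indeg_out
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) {
    cyc <- nodes[indeg_work > 0]
    stop("disease_dag: cycle among nodes {", paste(cyc, collapse = ", "), "}")
  }
  structure(list(nodes = nodes, parent_edges = parent_edges, parents = parents),
            class = "disease_dag")
}

#' Read a disease DAG from a child-parent TSV
#'
#' Rows are `child<TAB>parent`; `#` comments skipped. Acyclicity is verified;
#' cycles and self-loops are hard errors. An empty file yields an empty DAG.
#'
#' @param path Path to the TSV file.
#' @return A [disease_dag()].
#' @export
read_disease_dag <- function(path) {
  stopifnot(file.exists(path))
  rows <- read_tsv_rows(path)
  if (length(rows$lines) == 0) {
    return(disease_dag(character(0), matrix(character(0), ncol = 2)))
  }
  parts <- strsplit(rows$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    stop("read_disease_dag: malformed row at line ", rows$lineno[which(nf != 2)[[1]]])
  }
  edges <- cbind(vapply(parts, `[[`, character(1), 1),
                 vapply(parts, `[[`, character(1), 2))
  if (nrow(edges) > 0 && edges[1, 1] == "child" && edges[1, 2] == "parent") {
    edges <- edges[-1, , drop = FALSE]
  }
  disease_dag(unique(c(edges)), edges)
}

#' Write a disease DAG as a child-parent TSV
#' @param dag A [disease_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_dag <- function(dag, path) {
  e <- dag$parent_edges
  if (nrow(e) > 0) e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  writeLines(c("child\tparent", paste(e[, 1], e[, 2], sep = "\t")), path)
  invisible(path)
}

#' Root nodes of a disease DAG
#' @param dag A [disease_dag()].
#' @return Character vector of nodes with no parent.
#' @export
dag_roots <- function(dag) {
  dag$nodes[vapply(dag$parents[dag$nodes], length, integer(1)) == 0]
}

# ---- localisation matrices ---------------------------------------------------

#' Construct an entity x 7 compartment localisation matrix
#'
#' @param entity_ids Ordered entity identifiers.
#' @param labels Binary matrix with one column per compartment in the
#'   canonical [compartments()] order.
#' @return An object of class `localization_matrix`.
#' @export
localization_matrix <- function(entity_ids, labels) {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0, 1))) stop("localization_matrix: entries must be 0/1")
  if (ncol(labels) != 7) stop("localization_matrix: expected 7 compartments")
  if (nrow(labels) != length(entity_ids)) stop("localization_matrix: row mismatch")
  storage.mode(labels) <- "double"
  dimnames(labels) <- list(entity_ids, compartments())
  structure(list(entity_ids = as.character(entity_ids), labels = labels),
            class = "localization_matrix")
}

#' Read a localisation matrix from TSV
#'
#' Header must be `id` followed by the 7 compartments in canonical order;
#' any other header, or any entry outside \{0, 1\}, is a hard error.
#'
#' @param path Path to the TSV file.
#' @return A [localization_matrix()].
#' @export
read_localization <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   comment.char = "#")
  expected <- c("id", compartments())
  if (!identical(colnames(df), expected)) {
    stop("read_localization: header mismatch; expected ",
         paste(expected, collapse = ", "))
  }
  labels <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(labels))
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    stop("read_localization: entries must be 0 or 1")
  }
  localization_matrix(df$id, matrix(vals, nrow = nrow(df)))
}

#' Write a localisation matrix to TSV
#' @param loc A [localization_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization <- function(loc, path) {
  write_matrix_tsv(loc$labels, path)
}

# ---- generic numeric matrices ------------------------------------------------

#' Write a numeric matrix as TSV (bit-exact round-trip dialect)
#'
#' First column `id` holds row names; numeric cells are formatted with
#' `%.10g`, which round-trips the binary and similarity matrices used here.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c("id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path Path to the TSV file.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# ---- similarity / feature matrices -------------------------------------------

#' Construct a validated similarity matrix
#'
#' Symmetry (within 1e-9), unit diagonal and range `[0, 1]` are asserted on
#' every construction.
#'
#' @param ids Ordered identifiers (rows = columns).
#' @param values Square numeric matrix.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(ids, values) {
  values <- as.matrix(values)
  n <- length(ids)
  stopifnot(nrow(values) == n, ncol(values) == n)
  if (max(abs(values - t(values))) > 1e-9) {
    stop("similarity_matrix: not symmetric within 1e-9")
  }
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-9) {
    stop("similarity_matrix: diagonal must be 1")
  }
  diag(values) <- 1
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stop("similarity_matrix: values outside [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values),
            class = "similarity_matrix")
}

#' Construct a miRNA feature matrix for one model branch
#'
#' @param mirna_ids Ordered miRNA identifiers (canonical order).
#' @param values Numeric `length(mirna_ids)` x d matrix of finite entries.
#' @param branch One of `"seq"`, `"disease"`, `"drug"`, `"mrna_net"`,
#'   `"mrna_loc"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(mirna_ids, values, branch) {
  branch <- match.arg(branch, c("seq", "disease", "drug", "mrna_net", "mrna_loc"))
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(mirna_ids))
  if (!all(is.finite(values))) stop("feature_matrix: non-finite entries")
  rownames(values) <- mirna_ids
  structure(list(mirna_ids = as.character(mirna_ids), values = values,
                 branch = branch),
            class = "feature_matrix")
}

#' Align a miRNA-indexed object to the canonical miRNA order
#'
#' Reorders the miRNA rows of an [assoc_network()], [feature_matrix()] or
#' miRNA [localization_matrix()] to `mirna_ids`; any miRNA missing from the
#' object is a hard error.
#'
#' @param x Object to align.
#' @param mirna_ids Canonical order.
#' @return The object with rows reordered.
#' @export
align_to_mirnas <- function(x, mirna_ids) {
  ids <- if (inherits(x, "assoc_network") || inherits(x, "feature_matrix")) {
    x$mirna_ids
  } else if (inherits(x, "localization_matrix")) {
    x$entity_ids
  } else stop("align_to_mirnas: unsupported type")
  miss <- setdiff(mirna_ids, ids)
  if (length(miss) > 0) stop("align_to_mirnas: missing miRNA ", miss[[1]])
  ord <- match(mirna_ids, ids)
  if (inherits(x, "assoc_network")) {
    x$mirna_ids <- mirna_ids
    x$adjacency <- x$adjacency[ord, , drop = FALSE]
  } else if (inherits(x, "feature_matrix")) {
    x$mirna_ids <- mirna_ids
    x$values <- x$values[ord, , drop = FALSE]
  } else {
    x$entity_ids <- mirna_ids
    x$labels <- x$labels[ord, , drop = FALSE]
  }
  x
}
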
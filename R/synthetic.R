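# Synthetic benchmark generator: complete, internally consistent input
# bundles with a planted localisation signal, so every pipeline stage is
# testable without any external download.
#
# Shapes emulate (scaled down) a realistic benchmark: a few hundred miRNAs,
# tens of diseases and drugs, a few hundred mRNAs, bipartite densities of a
# few percent. The localisation signal is planted through the mRNA channel:
# K = 7 latent miRNA communities drive community-enriched associations, mRNA
# labels follow a community-to-compartment affinity, and miRNA labels
# (mostly) inherit the thresholded mRNA-localisation propagation.

#' Synthetic dataset configuration
#'
#' @param n_mirna,n_disease,n_drug,n_mrna Entity counts (all >= 2).
#' @param seq_len Length-2 integer range of miRNA sequence lengths.
#' @param dag_depth,dag_branching Shape of the random rooted disease DAG.
#' @param density_disease,density_drug,density_mrna Target edge densities of
#'   the three bipartite networks.
#' @param signal_strength Probability `beta` that a miRNA inherits the
#'   thresholded propagated mRNA-localisation signal (otherwise its labels
#'   are random).
#' @param label_noise Probability `eps` of flipping each label bit.
#' @param loc_threshold Threshold on the propagated fraction above which a
#'   compartment is inherited as a positive label.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_mirna = 300L, n_disease = 80L, n_drug = 20L,
                         n_mrna = 200L, seq_len = c(18L, 25L),
                         dag_depth = 4L, dag_branching = 3L,
                         density_disease = 0.04, density_drug = 0.05,
                         density_mrna = 0.04, signal_strength = 0.8,
                         label_noise = 0.05, loc_threshold = 0.4,
                         seed = 1L) {
  stopifnot(n_mirna >= 2, n_disease >= 2, n_drug >= 2, n_mrna >= 2,
            length(seq_len) == 2, seq_len[1] >= 6, seq_len[2] >= seq_len[1],
            signal_strength >= 0, signal_strength <= 1,
            label_noise >= 0, label_noise <= 1, dag_depth >= 2)
  structure(list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
                 n_drug = as.integer(n_drug), n_mrna = as.integer(n_mrna),
                 seq_len = as.integer(seq_len), dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 density_disease = density_disease, density_drug = density_drug,
                 density_mrna = density_mrna, signal_strength = signal_strength,
                 label_noise = label_noise, loc_threshold = loc_threshold,
                 seed = as.integer(seed)),
            class = "synth_config")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

# community-enriched Bernoulli bipartite adjacency; intra-community cells are
# 4x as likely as the baseline would suggest, inter-community cells 0.5x,
# which keeps the overall expected density at the target for 7 communities.
sample_bipartite <- function(cm_row, cm_col, density) {
  p <- matrix(0.5 * density, length(cm_row), length(cm_col))
  p[outer(cm_row, cm_col, `==`)] <- 4 * density
  p <- pmin(p, 1)
  matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
}

random_dag <- function(ids, depth, branching) {
  n <- length(ids)
  # level sizes proportional to branching^level, at least 1 root
  w <- branching^(seq_len(depth) - 1)
  sizes <- pmax(1L, round(n * w / sum(w)))
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n) sizes[depth] <- sizes[depth] + 1L
  level <- rep(seq_len(depth), sizes)
  edges <- NULL
  for (l in 2:depth) {
    children <- ids[level == l]
    parents_pool <- ids[level == l - 1]
    for (ch in children) {
      pa <- parents_pool[sample.int(length(parents_pool), 1)]
      edges <- rbind(edges, c(ch, pa))
      if (length(parents_pool) > 1 && runif(1) < 0.2) {
        pa2 <- sample(setdiff(parents_pool, pa), 1)
        edges <- rbind(edges, c(ch, pa2))
      }
    }
  }
  disease_dag(ids, edges)
}

#' Generate a synthetic input bundle with planted localisation signal
#'
#' Produces miRNA sequences (with one compartment motif per latent
#' community), a rooted disease DAG, three community-enriched bipartite
#' association networks, mRNA localisation labels driven by a
#' community-compartment affinity, and miRNA labels that inherit the
#' thresholded mRNA-propagation signal with probability `signal_strength`
#' (random otherwise), then flip each bit with probability `label_noise`.
#' Every compartment is guaranteed at least `max(10, 5% n)` positives and 10
#' negatives; the generator resamples (up to 100 draws) and errors if the
#' configuration cannot meet the guarantee.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `milocfuse_bundle`: `mirnas`, `dag`,
#'   `networks` (named list of [assoc_network()]), `mrna_loc`, `labels`,
#'   `communities`, and `cfg`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  K <- 7L
  n <- cfg$n_mirna
  mirna_ids <- pad_ids("mir", n)
  disease_ids <- pad_ids("dis", cfg$n_disease)
  drug_ids <- pad_ids("drg", cfg$n_drug)
  mrna_ids <- pad_ids("gen", cfg$n_mrna)

  cm_mirna <- sample.int(K, n, replace = TRUE)
  cm_disease <- sample.int(K, cfg$n_disease, replace = TRUE)
  cm_drug <- sample.int(K, cfg$n_drug, replace = TRUE)
  cm_mrna <- sample.int(K, cfg$n_mrna, replace = TRUE)

  # sequences: uniform RNA with the community motif injected (p = 0.9)
  motifs <- vapply(seq_len(K), function(k) {
    paste(sample(c("A", "C", "G", "U"), 6, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(seq(cfg$seq_len[1], cfg$seq_len[2]), 1)
    s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
    if (runif(1) < 0.9) {
      pos <- sample.int(len - 5L, 1)
      s[pos:(pos + 5L)] <- strsplit(motifs[cm_mirna[i]], "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))
  mirnas <- mirna_set(mirna_ids, setNames(seqs, mirna_ids))

  dag <- random_dag(disease_ids, cfg$dag_depth, cfg$dag_branching)

  mk_net <- function(cm_col, ids_col, kind, density) {
    adj <- sample_bipartite(cm_mirna, cm_col, density)
    dimnames(adj) <- list(mirna_ids, ids_col)
    assoc_network(mirna_ids, ids_col, kind, adj)
  }
  net_disease <- mk_net(cm_disease, disease_ids, "disease", cfg$density_disease)
  net_drug <- mk_net(cm_drug, drug_ids, "drug", cfg$density_drug)
  net_mrna <- mk_net(cm_mrna, mrna_ids, "mrna", cfg$density_mrna)

  # mRNA labels: each community has a primary and a secondary compartment
  # (real localisation data is strongly multi-label), plus a low background
  pl <- matrix(0.08, cfg$n_mrna, K)
  pl[cbind(seq_len(cfg$n_mrna), cm_mrna)] <- 0.9
  pl[cbind(seq_len(cfg$n_mrna), cm_mrna %% K + 1L)] <- 0.6
  Lm <- matrix(rbinom(length(pl), 1, pl), cfg$n_mrna, K)
  none <- rowSums(Lm) == 0
  Lm[cbind(which(none), cm_mrna[none])] <- 1
  mrna_loc <- localization_matrix(mrna_ids, Lm)

  prop <- propagate_mrna_localization(net_mrna, mrna_loc)$values
  planted <- (prop >= cfg$loc_threshold) * 1
  target_pos <- max(10, ceiling(0.05 * n))
  labels <- NULL
  for (attempt in seq_len(100)) {
    inherit <- runif(n) < cfg$signal_strength
    Y <- matrix(rbinom(n * K, 1, 0.25), n, K)
    Y[inherit, ] <- planted[inherit, ]
    flip <- matrix(runif(n * K) < cfg$label_noise, n, K)
    Y <- ifelse(flip, 1 - Y, Y)
    pos <- colSums(Y)
    if (all(pos >= target_pos) && all(n - pos >= 10)) {
      labels <- Y
      break
    }
  }
  if (is.null(labels)) {
    stop("generate_dataset: could not satisfy per-compartment label bounds ",
         "after 100 resamples; increase density or n_mirna")
  }
  structure(list(mirnas = mirnas, dag = dag,
                 networks = list(disease = net_disease, drug = net_drug,
                                 mrna = net_mrna),
                 mrna_loc = mrna_loc,
                 labels = localization_matrix(mirna_ids, labels),
                 communities = list(mirna = cm_mirna, disease = cm_disease,
                                    drug = cm_drug, mrna = cm_mrna),
                 planted = planted, cfg = cfg),
            class = "milocfuse_bundle")
}

#' @export
print.milocfuse_bundle <- function(x, ...) {
  cat("<milocfuse_bundle> ", length(x$mirnas$ids), " miRNAs, ",
      length(x$networks$disease$entity_ids), " diseases, ",
      length(x$networks$drug$entity_ids), " drugs, ",
      length(x$networks$mrna$entity_ids), " mRNAs (seed ", x$cfg$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a bundle to a directory of plain-text files
#'
#' Emits `mirna.fasta`, `disease_dag.tsv`, `mirna_disease.tsv`,
#' `mirna_drug.tsv`, `mirna_mrna.tsv`, `mrna_localization.tsv` and
#' `mirna_labels.tsv` in the formats the readers expect. Output is
#' byte-identical for identical configurations.
#'
#' @param bundle A `milocfuse_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mirna_fasta(bundle$mirnas, file.path(dir, "mirna.fasta"))
  write_disease_dag(bundle$dag, file.path(dir, "disease_dag.tsv"))
  write_edge_list(bundle$networks$disease, file.path(dir, "mirna_disease.tsv"))
  write_edge_list(bundle$networks$drug, file.path(dir, "mirna_drug.tsv"))
  write_edge_list(bundle$networks$mrna, file.path(dir, "mirna_mrna.tsv"))
  write_localization(bundle$mrna_loc, file.path(dir, "mrna_localization.tsv"))
  write_localization(bundle$labels, file.path(dir, "mirna_labels.tsv"))
  invisible(dir)
}

#' Read a bundle directory written by [write_dataset()]
#'
#' @param dir Directory containing the bundle files.
#' @return A `milocfuse_bundle` (without generator-only fields).
#' @export
read_dataset <- function(dir) {
  mirnas <- read_mirna_fasta(file.path(dir, "mirna.fasta"))
  dag <- read_disease_dag(file.path(dir, "disease_dag.tsv"))
  nets <- list(
    disease = read_edge_list(file.path(dir, "mirna_disease.tsv"), "disease",
                             mirnas$ids),
    drug = read_edge_list(file.path(dir, "mirna_drug.tsv"), "drug", mirnas$ids),
    mrna = read_edge_list(file.path(dir, "mirna_mrna.tsv"), "mrna", mirnas$ids)
  )
  mrna_loc <- read_localization(file.path(dir, "mrna_localization.tsv"))
  labels <- align_to_mirnas(read_localization(file.path(dir, "mirna_labels.tsv")),
                            mirnas$ids)
  structure(list(mirnas = mirnas, dag = dag, networks = nets,
                 mrna_loc = mrna_loc, labels = labels, cfg = NULL),
            class = "milocfuse_bundle")
}
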
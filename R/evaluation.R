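# Cross-validation drivers and per-compartment AUC/AUPR metrics.
#
# Similarity, embedding and propagation features are computed once on the
# full networks (the transductive pipeline order); only the classifier is
# retrained per fold, and metrics are computed on out-of-fold predictions
# pooled over all folds.

#' Random k-fold assignment
#'
#' A seeded random permutation split into k near-equal folds (sizes differ
#' by at most one); every index lands in exactly one fold.
#'
#' @param n Number of samples (`n >= k`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, length `n`.
#' @export
kfold_indices <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("kfold_indices: n < k")
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep_len(seq_len(k), n)
  fold
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney U statistic; tied scores count
#' one half. Returns `NA` with a warning when `y` has a single class.
#'
#' @param y Binary label vector.
#' @param s Numeric score vector.
#' @return AUC in `[0, 1]`, or `NA_real_`.
#' @export
roc_auc <- function(y, s) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(s), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("roc_auc: single-class labels, AUC undefined")
    return(NA_real_)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: summed precision
#' weighted by the recall increments over decreasing score thresholds
#' (tied scores form a single threshold).
#'
#' @param y Binary label vector.
#' @param s Numeric score vector.
#' @return Average precision in `[0, 1]`, or `NA_real_` for single-class `y`.
#' @export
pr_auc <- function(y, s) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(s), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) {
    warning("pr_auc: single-class labels, AUPR undefined")
    return(NA_real_)
  }
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  ss <- s[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE) # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

eval_predictions <- function(y, probs) {
  per_class <- purrr::map_dfr(seq_len(ncol(y)), function(j) {
    yj <- y[, j]
    if (length(unique(yj)) < 2) {
      warning("metrics undefined for single-class compartment ",
              compartments()[j], "; excluded from means")
      return(tibble::tibble(compartment = compartments()[j],
                            auc = NA_real_, aupr = NA_real_))
    }
    tibble::tibble(compartment = compartments()[j],
                   auc = roc_auc(yj, probs[, j]),
                   aupr = pr_auc(yj, probs[, j]))
  })
  list(per_class = per_class,
       mean_auc = mean(per_class$auc, na.rm = TRUE),
       mean_aupr = mean(per_class$aupr, na.rm = TRUE))
}

#' k-fold cross-validation of the localisation model
#'
#' Folds split miRNAs. For each fold the classifier (hypergraph weights,
#' projections, attention and MLP) is re-initialised and trained on the
#' other folds only, out-of-fold probabilities are collected, and after all
#' folds per-compartment AUC/AUPR are computed once on the pooled vectors.
#'
#' @param input A [model_input()] with labels.
#' @param config A [model_config()]; `config$seed` controls folds, inits,
#'   batching and dropout (each fold trains with seed `config$seed + fold`).
#' @param k Number of folds.
#' @return An object of class `milocfuse_cv`: `per_class` tibble,
#'   `mean_auc`, `mean_aupr`, `fold_assignments`, pooled `probs`, and the
#'   config used.
#' @export
cross_validate <- function(input, config = model_config(), k = 10L) {
  stopifnot(inherits(input, "model_input"), !is.null(input$y))
  n <- length(input$mirna_ids)
  fold <- kfold_indices(n, k, config$seed)
  probs <- matrix(NA_real_, n, 7, dimnames = list(input$mirna_ids, compartments()))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_localizer(input, cfg, train_idx = which(fold != f))
    probs[test_idx, ] <- predict_proba(fit, input, test_idx)$probs
  }
  stopifnot(!anyNA(probs)) # pooled out-of-fold predictions cover every miRNA
  ev <- eval_predictions(input$y, probs)
  structure(list(per_class = ev$per_class, mean_auc = ev$mean_auc,
                 mean_aupr = ev$mean_aupr, fold_assignments = fold,
                 probs = probs, config = config, k = k),
            class = "milocfuse_cv")
}

#' @export
print.milocfuse_cv <- function(x, ...) {
  cat("<milocfuse_cv> ", x$k, "-fold; mean AUC ", sprintf("%.4f", x$mean_auc),
      ", mean AUPR ", sprintf("%.4f", x$mean_aupr), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' Evaluate a trained model on held-out miRNAs
#'
#' Strict held-out evaluation: the model is trained on the complement of
#' `test_idx` and scored on `test_idx` only.
#'
#' @param input A [model_input()] with labels.
#' @param config A [model_config()].
#' @param test_idx Integer indices of the held-out miRNAs.
#' @return A list with `per_class`, `mean_auc`, `mean_aupr` and `probs`.
#' @export
independent_test <- function(input, config = model_config(), test_idx) {
  stopifnot(length(test_idx) > 0)
  fit <- train_localizer(input, config,
                         train_idx = setdiff(seq_along(input$mirna_ids), test_idx))
  probs <- predict_proba(fit, input, test_idx)$probs
  c(eval_predictions(input$y[test_idx, , drop = FALSE], probs),
    list(probs = probs))
}

#' Ablation experiments
#'
#' One [cross_validate()] run per flag set; the empty set reproduces the
#' full model wiring, `no_hypergraph` feeds raw node2vec features forward,
#' `no_cross_attention` mean-pools the projected branches, and the branch
#' flags remove feature families.
#'
#' @param features,hypergraphs,labels Passed to [model_input()] per variant.
#' @param config A [model_config()].
#' @param flag_sets List of character vectors of ablation flags.
#' @param k Folds per run.
#' @return A tibble with one row per variant (`flags`, `mean_auc`,
#'   `mean_aupr`, `cv` list-column).
#' @export
run_ablation <- function(features, hypergraphs, labels,
                         config = model_config(),
                         flag_sets = list(character(0), "no_hypergraph",
                                          "no_cross_attention"),
                         k = 10L) {
  purrr::map_dfr(flag_sets, function(flags) {
    cfg <- config
    cfg$ablation <- flags
    inp <- model_input(features, hypergraphs, labels, ablation = flags)
    cv <- cross_validate(inp, cfg, k)
    tibble::tibble(flags = paste(sort(flags), collapse = "+"),
                   mean_auc = cv$mean_auc, mean_aupr = cv$mean_aupr,
                   cv = list(cv))
  })
}

#' Sweep the number of hypergraph-convolution layers
#'
#' @param features,hypergraphs,labels Passed to [model_input()].
#' @param config A [model_config()].
#' @param layers Integer vector of layer counts to evaluate.
#' @param k Folds per run.
#' @return A tibble with one row per layer count.
#' @export
sweep_hg_layers <- function(features, hypergraphs, labels,
                            config = model_config(), layers = 1:4, k = 10L) {
  purrr::map_dfr(layers, function(L) {
    cfg <- config
    cfg$hg_layers <- as.integer(L)
    inp <- model_input(features, hypergraphs, labels, ablation = cfg$ablation)
    cv <- cross_validate(inp, cfg, k)
    tibble::tibble(hg_layers = L, mean_auc = cv$mean_auc,
                   mean_aupr = cv$mean_aupr, cv = list(cv))
  })
}
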
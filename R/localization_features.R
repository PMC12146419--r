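# Fifth feature branch: mRNA subcellular annotations propagated to miRNAs
# through the miRNA-mRNA association network.

#' Propagate mRNA localisation annotations to miRNAs
#'
#' Each miRNA's 7-dimensional localisation evidence is the row-normalised
#' average of its partner mRNAs' binary label rows (`"mean"`), i.e. the
#' fraction of partners annotated to each compartment; `"count"` skips the
#' normalisation. miRNAs without partners get a zero row.
#'
#' @param assoc An [assoc_network()] with `entity_kind = "mrna"`.
#' @param loc A [localization_matrix()] covering every mRNA in `assoc`.
#' @param mode `"mean"` (default) or `"count"`.
#' @return A [feature_matrix()] (branch `"mrna_loc"`, 7 columns); entries lie
#'   in `[0, 1]` in `"mean"` mode.
#' @export
propagate_mrna_localization <- function(assoc, loc, mode = c("mean", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(assoc, "assoc_network"), inherits(loc, "localization_matrix"))
  if (assoc$entity_kind != "mrna") {
    stop("propagate_mrna_localization: entity_kind must be 'mrna'")
  }
  miss <- setdiff(assoc$entity_ids, loc$entity_ids)
  if (length(miss) > 0) {
    stop("propagate_mrna_localization: mRNA missing from localisation matrix: ",
         miss[[1]])
  }
  A <- assoc$adjacency
  L <- loc$labels[assoc$entity_ids, , drop = FALSE]
  X <- A %*% L
  if (mode == "mean") {
    deg <- rowSums(A)
    X <- X / ifelse(deg > 0, deg, 1)
  }
  colnames(X) <- compartments()
  feature_matrix(assoc$mirna_ids, X, "mrna_loc")
}
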
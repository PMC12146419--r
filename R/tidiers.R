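# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a cross-validation report
#'
#' @param x A `milocfuse_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per compartment (`compartment`, `auc`,
#'   `aupr`).
#' @export
tidy.milocfuse_cv <- function(x, ...) x$per_class

#' One-row summary of a cross-validation report
#'
#' @param x A `milocfuse_cv` object.
#' @param ... Unused.
#' @return A tibble with `k`, `n`, `mean_auc`, `mean_aupr`.
#' @export
glance.milocfuse_cv <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$fold_assignments),
                 mean_auc = x$mean_auc, mean_aupr = x$mean_aupr)
}

#' Tidy a trained model's history
#'
#' @param x A `milocfuse_model` object.
#' @param ... Unused.
#' @return The per-epoch train/validation loss tibble.
#' @export
tidy.milocfuse_model <- function(x, ...) x$history

#' One-row summary of a trained model
#'
#' @param x A `milocfuse_model` object.
#' @param ... Unused.
#' @return A tibble with `epochs`, `best_epoch`, `best_val_loss` and
#'   `n_parameters`.
#' @export
glance.milocfuse_model <- function(x, ...) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  best_val <- if (nrow(x$history) && x$best_epoch > 0 &&
                  any(is.finite(x$history$val_loss))) {
    x$history$val_loss[x$best_epoch]
  } else NA_real_
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = best_val, n_parameters = count(x$params))
}

#' Tidy a prediction matrix into long format
#'
#' @param x A `milocfuse_prediction` object.
#' @param ... Unused.
#' @return A tibble with `mirna_id`, `compartment`, `prob`.
#' @export
tidy.milocfuse_prediction <- function(x, ...) {
  tibble::as_tibble(x$probs, rownames = "mirna_id") |>
    tidyr::pivot_longer(-"mirna_id", names_to = "compartment",
                        values_to = "prob")
}

#' Plot per-compartment AUC and AUPR of a cross-validation report
#'
#' @param object A `milocfuse_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.milocfuse_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("auc", "aupr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compartment, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "pooled out-of-fold metric",
                  title = sprintf("%d-fold CV: mean AUC %.3f, mean AUPR %.3f",
                                  object$k, object$mean_auc, object$mean_aupr)) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted model
#'
#' @param object A `milocfuse_model` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.milocfuse_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch", names_to = "split",
                            values_to = "loss")
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}
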